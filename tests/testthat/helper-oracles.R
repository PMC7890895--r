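# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: per-base set arithmetic, literal rule loops, exact
# enumeration and closed forms.

bases_of <- function(row) seq(row$start, row$end - 1) # 0-based positions

shared_bases <- function(a, b) {
  if (a$seq_id != b$seq_id) return(0L)
  length(intersect(bases_of(a), bases_of(b)))
}

# literal per-base implementation of the signature-calling rules
brute_classify <- function(k4me3, k27ac, k4me1, min_frac = 0.5) {
  rowlist <- function(x) if (nrow(x)) lapply(seq_len(nrow(x)), function(i) x[i, ]) else list()
  me3 <- rowlist(k4me3); ac <- rowlist(k27ac); me1 <- rowlist(k4me1)
  ap_idx <- integer(0)
  excl_bases <- list() # per seq_id
  add_excl <- function(row) {
    key <- row$seq_id
    excl_bases[[key]] <<- union(excl_bases[[key]], bases_of(row))
  }
  for (i in seq_along(me3)) {
    covered <- any(vapply(ac, function(q) {
      shared_bases(me3[[i]], q) >= min_frac * (me3[[i]]$end - me3[[i]]$start)
    }, logical(1)))
    if (covered) {
      ap_idx <- c(ap_idx, i)
      add_excl(me3[[i]])
      for (q in ac) if (shared_bases(me3[[i]], q) >= 1) add_excl(q)
    }
  }
  ae_idx <- integer(0)
  for (j in seq_along(ac)) {
    key <- ac[[j]]$seq_id
    in_excl <- length(intersect(bases_of(ac[[j]]), excl_bases[[key]])) >= 1
    if (in_excl) next
    covered <- any(vapply(me1, function(m) {
      shared_bases(ac[[j]], m) >= min_frac * (ac[[j]]$end - ac[[j]]$start)
    }, logical(1)))
    if (covered) ae_idx <- c(ae_idx, j)
  }
  pe_idx <- integer(0)
  for (m in seq_along(me1)) {
    touched <- any(vapply(c(ac, me3), function(x) shared_bases(me1[[m]], x) >= 1,
                          logical(1)))
    if (!touched) pe_idx <- c(pe_idx, m)
  }
  dplyr::bind_rows(
    tibble::tibble(seq_id = character(), start = integer(), end = integer(),
                   signature = character()),
    if (length(ap_idx)) dplyr::mutate(k4me3[ap_idx, ], signature = "AP"),
    if (length(ae_idx)) dplyr::mutate(k27ac[ae_idx, ], signature = "AE"),
    if (length(pe_idx)) dplyr::mutate(k4me1[pe_idx, ], signature = "PE")
  )
}

# literal per-base cross-tissue activity: either region covered >= 50% of
# its own length by the other, same signature, different tissue
brute_activity_tissues <- function(regulome, min_frac = 0.5) {
  n <- nrow(regulome)
  acts <- lapply(seq_len(n), function(i) regulome$tissue[i])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- regulome[i, ]; b <- regulome[j, ]
      if (a$tissue == b$tissue || a$signature != b$signature) next
      sb <- shared_bases(a, b)
      if (sb >= min_frac * (a$end - a$start) || sb >= min_frac * (b$end - b$start)) {
        acts[[i]] <- union(acts[[i]], b$tissue)
      }
    }
  }
  vapply(acts, function(z) paste(sort(z), collapse = ","), character(1))
}

# per-base union of intervals over a toy sequence
brute_union_bases <- function(x) {
  out <- list()
  for (i in seq_len(nrow(x))) {
    key <- x$seq_id[i]
    out[[key]] <- union(out[[key]], bases_of(x[i, ]))
  }
  out
}

# integer matrix power by repeated multiplication
matpow_int <- function(P, t) {
  out <- diag(nrow(P))
  for (k in seq_len(t)) out <- out %*% P
  dimnames(out) <- dimnames(P)
  out
}

# expected parsimony transition estimate under a per-MY switch matrix on the
# triad topology ((a:t_tip, b:t_tip):t_in, out:t_out): enumerate all 27
# (sig_a, sig_b, sig_out) outcomes, apply the parsimony counting rules, and
# normalise the expected counts
triad_parsimony_expectation <- function(per_my, pi0, t_tip, t_in, t_out) {
  sigs <- c("AP", "AE", "PE")
  M_tip <- matpow_int(per_my, t_tip)
  M_in <- matpow_int(per_my, t_in)
  M_out <- matpow_int(per_my, t_out)
  counts <- matrix(0, 3, 3, dimnames = list(sigs, sigs))
  for (a in sigs) for (b in sigs) for (o in sigs) {
    p <- 0
    for (z in sigs) {
      pz <- pi0[z] * M_out[z, o]
      inner <- 0
      for (w in sigs) inner <- inner + M_in[z, w] * M_tip[w, a] * M_tip[w, b]
      p <- p + pz * inner
    }
    # parsimony rules: stay when a == b == o; single switch o -> other when
    # {a, b} = {o, other}
    if (a == o && b == o) {
      counts[o, o] <- counts[o, o] + p
    } else if (a == o && b != o) {
      counts[o, b] <- counts[o, b] + p
    } else if (b == o && a != o) {
      counts[o, a] <- counts[o, a] + p
    }
  }
  counts / rowSums(counts)
}

# Pearson chi-square p for a 2x2 table of (hit, miss) x (A, B)
chisq_2x2_p <- function(x1, n1, x2, n2, correct = FALSE) {
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- if (correct) pmax(0, abs(tab - E) - 0.5) else abs(tab - E)
  stat <- sum(adj^2 / E)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# exact one-sided Mann-Whitney p by enumeration of all rank assignments
wilcox_enum_p <- function(x, y, alternative = "greater") {
  all_v <- c(x, y)
  n1 <- length(x)
  obs <- sum(rank(all_v)[seq_len(n1)])
  combos <- utils::combn(length(all_v), n1)
  rk <- rank(all_v)
  sums <- apply(combos, 2, function(ii) sum(rk[ii]))
  if (alternative == "greater") mean(sums >= obs) else mean(sums <= obs)
}

# ordinary least squares through the normal equations
normal_equations_fit <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
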