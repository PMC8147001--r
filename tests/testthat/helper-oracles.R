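# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (character loops, explicit sums of squares) so they share no code
# path with the implementation they check.

# Random aligned protein fixture: n taxa x L columns with a given gap rate.
random_alignment <- function(n = 10, L = 60, gap_rate = 0.1, locus = "locus1") {
  chars <- c(protrate:::AA_LETTERS)
  members <- vapply(seq_len(n), function(i) {
    s <- sample(chars, L, replace = TRUE)
    gaps <- stats::runif(L) < gap_rate
    s[gaps] <- "-"
    paste(s, collapse = "")
  }, character(1))
  names(members) <- paste0("t", seq_len(n))
  locus_alignment(locus, members)
}

# Naive per-site p-distance: explicit column loop, no vectorization.
oracle_p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  aa <- protrate:::AA_LETTERS
  n <- 0L; mism <- 0L
  for (k in seq_along(ca)) {
    if ((ca[k] %in% aa) && (cb[k] %in% aa)) {
      n <- n + 1L
      if (ca[k] != cb[k]) mism <- mism + 1L
    }
  }
  if (n == 0) return(list(p = NA_real_, n_sites = 0L))
  list(p = mism / n, n_sites = n)
}

# Hand-written one-way ANOVA + Tukey-Kramer via the studentized range.
oracle_anova_tukey <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - gm)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fv, k - 1, n - k, lower.tail = FALSE)
  s2 <- ssw / (n - k)
  combs <- utils::combn(k, 2)
  tukey <- matrix(NA_real_, ncol(combs), 2,
                  dimnames = list(NULL, c("diff", "p_adj")))
  for (col in seq_len(ncol(combs))) {
    i <- combs[2, col]; j <- combs[1, col]   # TukeyHSD orders "later-earlier"
    se <- sqrt(s2 / 2 * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
    q <- abs(means[i] - means[j]) / se
    tukey[col, "diff"] <- unname(means[i] - means[j])
    tukey[col, "p_adj"] <- stats::ptukey(q, k, n - k, lower.tail = FALSE)
  }
  list(F = Fv, p_value = p, df_between = k - 1, df_within = n - k,
       tukey = tukey)
}

# Random additive distance matrix from a random tree with positive
# branch lengths; returns both.
random_additive_matrix <- function(n) {
  phy <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  phy <- ape::unroot(phy)
  list(tree = phy, d = ape::cophenetic.phylo(phy))
}

# Brute-force sliding-window IQ motif scan: tests every start position
# against the class definitions character by character.
oracle_iq_starts <- function(seq, class = c("IQ_full", "IQ_like")) {
  class <- match.arg(class)
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  len <- if (class == "IQ_full") 11L else 10L
  lead <- if (class == "IQ_full") c("F", "I", "L", "V") else c("F", "I", "L", "V", "M")
  starts <- integer(0)
  for (s in seq_len(max(L - len + 1, 0))) {
    w <- ch[s:(s + len - 1)]
    ok <- w[1] %in% lead && w[2] == "Q" && w[6] %in% c("R", "K")
    if (class == "IQ_full") ok <- ok && w[7] == "G" && w[11] %in% c("R", "K")
    if (ok) starts <- c(starts, s)
  }
  starts
}

# Small two-clade alignment with uniform split signal: every column
# separates group 1 from group 2.
two_group_alignment <- function(n_per_group = 3, L = 40) {
  g1 <- strrep("A", L)
  g2 <- strrep("W", L)
  members <- c(stats::setNames(rep(g1, n_per_group), paste0("a", seq_len(n_per_group))),
               stats::setNames(rep(g2, n_per_group), paste0("b", seq_len(n_per_group))))
  # add a little within-group noise so the matrix is not degenerate
  noise <- function(s, pos, res) {
    substr(s, pos, pos) <- res
    s
  }
  members[1] <- noise(members[1], 1, "C")
  members[n_per_group + 1] <- noise(members[n_per_group + 1], 1, "Y")
  locus_alignment("split", members)
}
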