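# Independent brute-force oracles used to validate the statistical routines.
# Each recomputes its quantity by a different route than the implementation.

# AUC by exhaustive enumeration of all positive/negative pairs.
auc_paircount <- function(scores, labels) {
  labels <- as.logical(labels)
  x <- scores[labels]; y <- scores[!labels]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# DeLong variance of a single AUC via the grouped (within-class) delete-one
# jackknife, recomputing the AUC from scratch for every deletion.
delong_var_jackknife <- function(scores, labels) {
  labels <- as.logical(labels)
  auc_full <- auc_paircount(scores, labels)
  jack_class <- function(positive) {
    idx <- which(labels == positive)
    n <- length(idx)
    loo <- vapply(idx, function(i) {
      auc_paircount(scores[-i], labels[-i])
    }, numeric(1))
    pseudo <- n * auc_full - (n - 1) * loo
    stats::var(pseudo) / n
  }
  jack_class(TRUE) + jack_class(FALSE)
}

# Placement values written out longhand (used to express the DeLong
# variance when checking it against the jackknife).
placements_for_test <- function(scores, labels) {
  labels <- as.logical(labels)
  x <- scores[labels]; y <- scores[!labels]
  list(v10 = vapply(x, function(a) mean((a > y) + 0.5 * (a == y)),
                    numeric(1)),
       v01 = vapply(y, function(b) mean((x > b) + 0.5 * (x == b)),
                    numeric(1)))
}

# Fleiss' P-bar via explicit pair counting: for each item, the proportion of
# agreeing rater pairs among all pairs.
fleiss_kappa_pairs <- function(R) {
  m <- unique(rowSums(R))
  agree <- apply(R, 1, function(cnt) {
    sum(choose(cnt, 2)) / choose(m, 2)
  })
  pj <- colSums(R) / sum(R)
  pe <- sum(pj^2)
  (mean(agree) - pe) / (1 - pe)
}

# One-way ANOVA F from the sum-of-squares decomposition written out by hand.
anova_F_ss <- function(groups) {
  all_y <- unlist(groups)
  grand <- mean(all_y)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(all_y) - length(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# Fisher's exact p for a 2x2 table by exhaustive hypergeometric enumeration.
fisher_p_enum <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Minimal feature set builders used across tests.
features_with <- function(...) {
  vals <- list(...)
  f <- new_features()
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (isFALSE(v)) {
      f <- feat_set(f, nm, value = FALSE, status = "absent")
    } else {
      f <- feat_set(f, nm, value = v)
    }
  }
  f
}

default_kg <- local({
  kg <- NULL
  function() {
    if (is.null(kg)) kg <<- build_knowledge_graph()
    kg
  }
})
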