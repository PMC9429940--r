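# Inferential layer: Mantel correlations between method-specific distance
# matrices, PERMANOVA for the two-group (ridge/runnel style) contrast, and
# Hellinger + CCA with both-direction stepwise driver selection. Mantel and
# PERMANOVA are permutation tests with the +1 convention implemented here
# (vectorised over permutations); CCA and the stepwise search are delegated
# to vegan (cca / ordistep) behind this module's surface.

lower_tri <- function(D) D[lower.tri(D)]

# run seeded code without disturbing the caller's RNG stream, so
# simulation loops interleaving data generation with permutation tests
# stay independent
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Mantel permutation test between two distance matrices
#'
#' `r` is the Pearson correlation of the strictly-lower-triangle entries;
#' the null distribution permutes one matrix's label order `n_perm` times.
#' The two-sided p-value uses the +1 convention
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1)`; the one-sided
#' alternative counts `r_perm >= r_obs`.
#'
#' @param D1,D2 distance matrices with identical labels in identical order
#'   (n >= 4).
#' @param n_perm permutations (default 9999).
#' @param alternative `"two-sided"` (default) or `"greater"`.
#' @param seed integer seed.
#' @return object of class `mantel_result` with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 9999,
                        alternative = c("two-sided", "greater"), seed = 1) {
  alternative <- match.arg(alternative)
  if (!identical(rownames(D1), rownames(D2)) || is.null(rownames(D1))) {
    abort("distance matrices must carry identical labels in identical order")
  }
  n <- nrow(D1)
  if (n < 4) abort("need at least 4 samples")
  v1 <- lower_tri(D1)
  v2 <- lower_tri(D2)
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("constant distance matrix: Mantel correlation undefined")
  }
  r_obs <- cor(v1, v2)
  idx <- which(lower.tri(D1), arr.ind = TRUE)
  P <- with_local_seed(seed, {
    P0 <- matrix(0L, n_perm, n)
    for (k in seq_len(n_perm)) P0[k, ] <- sample.int(n)
    P0
  })
  I <- P[, idx[, 1], drop = FALSE]
  J <- P[, idx[, 2], drop = FALSE]
  X <- matrix(D2[(J - 1L) * n + I], n_perm, length(v1))
  v1c <- v1 - mean(v1)
  Xc <- X - rowMeans(X)
  r_perm <- as.vector(Xc %*% v1c) /
    (sqrt(rowSums(Xc^2)) * sqrt(sum(v1c^2)))
  exceed <- if (alternative == "two-sided") {
    sum(abs(r_perm) >= abs(r_obs) - 1e-12)
  } else {
    sum(r_perm >= r_obs - 1e-12)
  }
  structure(
    list(r = r_obs, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm,
         alternative = alternative),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' PERMANOVA for a grouping factor on a distance matrix
#'
#' Distance-based sums of squares: `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, pseudo-F
#' `(SS_between / (g - 1)) / (SS_within / (n - g))` and
#' `R^2 = SS_between / SS_total`. The p-value permutes group labels with
#' the +1 convention.
#'
#' @param D distance matrix with sample labels.
#' @param groups named vector or factor of group labels (>= 2 groups, each
#'   with >= 2 samples).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return object of class `permanova_result` with `pseudo_F`, `R2`, `p`,
#'   `n_perm`.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = 1) {
  n <- nrow(D)
  if (!is.null(names(groups))) groups <- groups[rownames(D)]
  g <- as.factor(groups)
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("need >= 2 groups with >= 2 samples each")
  }
  M2 <- D^2
  ss_total <- sum(lower_tri(M2)) / n
  k <- length(sizes)
  ss_within_for <- function(lab) {
    # 0.5 * sum over same-group pairs of d^2, per group, / n_g
    Z <- stats::model.matrix(~ lab - 1)
    sum(colSums(Z * (M2 %*% Z)) / (2 * colSums(Z)))
  }
  ss_within <- ss_within_for(g)
  ss_between <- ss_total - ss_within
  f_obs <- (ss_between / (k - 1)) / (ss_within / (n - k))
  # vectorised permutation of labels: indicator matmuls per group
  levs <- levels(g)
  Zp <- with_local_seed(seed, {
    Z0 <- matrix(0, n, n_perm * k)
    for (p in seq_len(n_perm)) {
      gp <- g[sample.int(n)]
      for (j in seq_len(k)) {
        Z0[, (p - 1L) * k + j] <- as.numeric(gp == levs[j])
      }
    }
    Z0
  })
  W <- colSums(Zp * (M2 %*% Zp)) / (2 * colSums(Zp))
  ssw_perm <- colSums(matrix(W, nrow = k))
  f_perm <- ((ss_total - ssw_perm) / (k - 1)) / (ssw_perm / (n - k))
  p_val <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_perm + 1)
  structure(
    list(pseudo_F = f_obs, R2 = ss_between / ss_total, p = p_val,
         n_perm = n_perm, ss_total = ss_total, ss_within = ss_within),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova_result> pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' Hellinger transformation of a count table
#'
#' Each entry becomes `sqrt(count / row total)` (rows are samples), via
#' `vegan::decostand`.
#'
#' @param x samples x features matrix or data frame of non-negative counts
#'   with positive row sums.
#' @return transformed matrix.
#' @export
hellinger <- function(x) {
  m <- as.matrix(x)
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(rowSums(m) == 0)) abort("zero row: Hellinger undefined")
  vegan::decostand(m, method = "hellinger")
}

#' Canonical correspondence analysis of a community on constraints
#'
#' Chi-square-standardised community table projected (row-weighted least
#' squares) onto centred/scaled constraints; fitted via `vegan::cca`.
#'
#' @param response samples x features non-negative table (commonly
#'   Hellinger-transformed counts).
#' @param constraints data frame of numeric covariates, rows aligned with
#'   `response`; centred and scaled internally.
#' @return object of class `cca_model`: the vegan fit plus `eigenvalues`
#'   (constrained), `total_inertia`, `constrained_inertia`.
#' @export
cca_fit <- function(response, constraints) {
  X <- as.data.frame(scale(as.matrix(constraints)))
  if (qr(as.matrix(X))$rank < ncol(X)) {
    abort(c("rank-deficient constraints",
            paste("columns:", paste(colnames(X), collapse = ", "))))
  }
  if (ncol(X) >= nrow(X)) abort("need fewer constraints than samples")
  fit <- vegan::cca(as.matrix(response) ~ ., data = X)
  structure(
    list(fit = fit,
         eigenvalues = unname(fit$CCA$eig),
         total_inertia = fit$tot.chi,
         constrained_inertia = fit$CCA$tot.chi,
         variables = colnames(X)),
    class = "cca_model"
  )
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model> constrained inertia %.4f of %.4f total (%d variables)\n",
              x$constrained_inertia, x$total_inertia, length(x$variables)))
  invisible(x)
}

#' Both-direction stepwise driver selection for CCA
#'
#' Starting from the unconstrained model, variables are added when their
#' marginal permutation p-value is at most `p_in` (smallest p first) and
#' dropped when it rises above `p_out`, iterating to a fixed point -
#' `vegan::ordistep(direction = "both")` under a fixed seed.
#'
#' @inheritParams cca_fit
#' @param p_in,p_out inclusion/exclusion thresholds (defaults 0.05 / 0.10).
#' @param n_perm permutations per marginal test (default 199).
#' @param seed integer seed (the selection path is deterministic given it).
#' @return `cca_model` of the selected fit, with a `selected` tibble
#'   (variable, p-value at inclusion test).
#' @export
stepwise_select <- function(response, constraints, p_in = 0.05, p_out = 0.10,
                            n_perm = 199, seed = 1) {
  X <- as.data.frame(scale(as.matrix(constraints)))
  set.seed(seed)
  # ordistep re-evaluates `cca` calls inside the formula environment, so
  # the models are built in an environment that carries cca and the data
  e <- new.env(parent = baseenv())
  e$cca <- vegan::cca
  e$.Y <- as.matrix(response)
  e$.X <- X
  m0 <- suppressWarnings(suppressMessages(
    eval(str2lang("cca(.Y ~ 1, data = .X)"), e)))
  scope_fml <- stats::as.formula(
    paste(".Y ~", paste(colnames(X), collapse = " + ")), env = e)
  sel <- suppressWarnings(suppressMessages(
    vegan::ordistep(m0, scope = scope_fml, direction = "both",
                    Pin = p_in, Pout = p_out,
                    permutations = n_perm, trace = FALSE)))
  vars <- attr(stats::terms(sel), "term.labels")
  anova_tab <- sel$anova
  selected <- if (length(vars) == 0) {
    tibble(variable = character(0), p = numeric(0))
  } else if (!is.null(anova_tab)) {
    steps <- rownames(anova_tab)
    tibble(variable = vars,
           p = map_dbl(vars, function(v) {
             hit <- grep(paste0("\\+ ", v, "$"), steps)
             if (length(hit) > 0) anova_tab$`Pr(>F)`[hit[length(hit)]] else NA_real_
           }))
  } else {
    tibble(variable = vars, p = NA_real_)
  }
  out <- structure(
    list(fit = sel,
         eigenvalues = if (is.null(sel$CCA)) numeric(0) else unname(sel$CCA$eig),
         total_inertia = sel$tot.chi,
         constrained_inertia = if (is.null(sel$CCA)) 0 else sel$CCA$tot.chi,
         variables = vars, selected = selected),
    class = "cca_model"
  )
  out
}
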