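#' Test-result container
#'
#' @param statistic named statistic value.
#' @param p two-sided p value.
#' @param dof degrees of freedom (possibly fractional) or NA.
#' @param method description string.
#' @param n sample sizes.
#' @param extra optional named list of extra fields.
#' @return `test_result` (list).
#' @keywords internal
test_result <- function(statistic, p, dof = NA_real_, method = "", n = NULL,
                        extra = list()) {
  structure(c(list(statistic = statistic, p = p, dof = dof,
                   method = method, n = n), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": ", names(x$statistic), " = ",
      signif(unname(x$statistic), 5),
      if (!all(is.na(x$dof))) paste0(", df = ",
                                     paste(signif(x$dof, 5), collapse = ", ")),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

# U statistic of sample x against y (number of (x_i, y_j) pairs with
# x_i > y_j, ties counting 1/2)
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
}

#' Mann–Whitney U test
#'
#' Reports `U = min(U_x, U_y)`.  For `n_x + n_y <= exact_max` (default 12)
#' and tie-free data the two-sided p is computed by full enumeration of all
#' group labelings; otherwise the normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max total sample size up to which the exact branch is used.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   branch.
#' @return `test_result` with statistic `U`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L, exact = NULL) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  nx <- length(x); ny <- length(y)
  ux <- u_statistic(x, y)
  uy <- nx * ny - ux
  u <- min(ux, uy)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (nx + ny) <= exact_max && !ties
  if (exact) {
    pool <- c(x, y)
    combs <- utils::combn(nx + ny, nx)
    us <- apply(combs, 2, function(idx)
      u_statistic(pool[idx], pool[-idx]))
    p <- min(1, 2 * min(mean(us <= ux), mean(us >= ux)))
    return(test_result(c(U = u), p, method = "Mann-Whitney U (exact)",
                       n = c(nx, ny)))
  }
  N <- nx + ny
  r <- rank(c(x, y))
  tie_sizes <- table(r)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) stop("all observations tied: U test undefined")
  mu <- nx * ny / 2
  z <- (ux - mu - sign(ux - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result(c(U = u), p, method = "Mann-Whitney U (normal approx.)",
              n = c(nx, ny))
}

#' Two-sample t test (Student or Welch)
#'
#' @param x,y numeric samples, `n >= 2` each.
#' @param welch use the Welch form with Satterthwaite df (default TRUE; the
#'   fractional dfs in the emulated analyses indicate Welch).
#' @return `test_result` with statistic `t`.
#' @export
t_test2 <- function(x, y, welch = TRUE) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L, ny >= 2L)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) stop("zero variance in both groups")
  if (welch) {
    se2 <- vx / nx + vy / ny
    tval <- (mean(x) - mean(y)) / sqrt(se2)
    dof <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    method <- "Welch t test"
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    dof <- nx + ny - 2
    method <- "Student t test"
  }
  p <- 2 * stats::pt(-abs(tval), dof)
  test_result(c(t = tval), p, dof = dof, method = method, n = c(nx, ny))
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks.  For `n <= exact_max`
#' (default 8) the two-sided p is computed by full enumeration of all `n!`
#' permutations of one variable; otherwise by the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y paired samples, `n >= 4`.
#' @param exact_max sample size up to which the exact branch is used.
#' @param exact force or auto-select (`NULL`) the exact branch.
#' @return `test_result` with statistic `rho`.
#' @export
spearman_cor <- function(x, y, exact_max = 8L, exact = NULL) {
  n <- length(x)
  stopifnot(n == length(y), n >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (is.null(exact)) exact <- n <= exact_max
  if (exact) {
    perms <- permutations_n(n)
    # Pearson on ranks for every permutation, vectorized:
    # rho = (sum(rx*ry_perm) - n*mean(rx)*mean(ry)) / ((n-1)*sd(rx)*sd(ry))
    cross <- matrix(ry[perms], nrow(perms), n) %*% rx
    rhos <- (cross - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(test_result(c(rho = rho), p,
                       method = "Spearman correlation (exact)", n = n))
  }
  # t approximation with a continuity correction of half the rho-lattice
  # step 12/(n^3 - n), which keeps the approximate p within 0.02 of the
  # exact enumeration at the crossover sample size
  rho_c <- sign(rho) * max(0, abs(rho) - 6 / (n^3 - n))
  tval <- rho_c * sqrt((n - 2) / max(1e-12, 1 - rho_c^2))
  p <- 2 * stats::pt(-abs(tval), n - 2)
  test_result(c(rho = rho), min(1, p), dof = n - 2,
              method = "Spearman correlation (t approx.)", n = n)
}

# all permutations of 1..n as an (n! x n) matrix
permutations_n <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_n(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# residual sum of squares of a least-squares fit
rss_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Two-way ANOVA with Type-II sums of squares
#'
#' Factorial ANOVA for two crossed between-subject factors (e.g. pregnancy
#' status and treatment), using Type-II sums of squares so that unbalanced
#' group sizes are handled: each main effect is adjusted for the other main
#' effect, and the interaction for both.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (coerced).
#' @return list of `test_result` for `A`, `B`, and `A:B`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (any(table(a, b) == 0)) stop("empty cell in the two-way design")
  y <- as.numeric(values)
  Xa <- stats::model.matrix(~a)
  Xb <- stats::model.matrix(~b)
  Xab <- stats::model.matrix(~ a + b)
  Xfull <- stats::model.matrix(~ a * b)
  rss_b <- rss_fit(Xb, y)
  rss_a <- rss_fit(Xa, y)
  rss_ab <- rss_fit(Xab, y)
  rss_full <- rss_fit(Xfull, y)
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_int <- df_a * df_b
  df_err <- length(y) - nlevels(a) * nlevels(b)
  if (df_err <= 0) stop("need >= 2 observations per cell")
  mse <- rss_full / df_err
  mk <- function(ss, df, label) {
    f <- (ss / df) / mse
    test_result(c(F = f), stats::pf(f, df, df_err, lower.tail = FALSE),
                dof = c(df, df_err),
                method = paste0("two-way ANOVA (Type II), ", label),
                extra = list(ss = ss))
  }
  list(A = mk(rss_b - rss_ab, df_a, "factor A"),
       B = mk(rss_a - rss_ab, df_b, "factor B"),
       AB = mk(rss_ab - rss_full, df_int, "interaction"))
}

#' Mixed (split-plot) ANOVA
#'
#' One between-subject factor (e.g. treatment) and one within-subject
#' factor (e.g. Sholl radius), one observation per subject x level, with
#' complete within-subject profiles.  The between effect is tested over
#' the subject error; the within effect and the interaction over the
#' subject x within error.  With `log_transform = TRUE` the response is
#' `log10(y + 1)` first (the transform used for intersection counts, which
#' include zeros at large radii).  Greenhouse–Geisser corrected p values
#' for the within and interaction effects are reported alongside the
#' uncorrected ones.
#'
#' @param values numeric response.
#' @param between between-subject factor.
#' @param within within-subject factor.
#' @param subject subject identifier.
#' @param log_transform apply `log10(y + 1)` first.
#' @return list of `test_result` for `between`, `within`, `interaction`;
#'   each within-type result carries `p_gg` and `epsilon_gg`.
#' @export
mixed_anova <- function(values, between, within, subject,
                        log_transform = FALSE) {
  g <- factor(between); w <- factor(within); s <- factor(subject)
  y <- as.numeric(values)
  stopifnot(length(y) == length(g), length(y) == length(w),
            length(y) == length(s))
  if (log_transform) y <- log10(y + 1)
  tab <- table(s, w)
  if (any(tab != 1L))
    stop("need exactly one observation per subject x within level")
  subj_group <- vapply(split(as.character(g), s), function(v) {
    u <- unique(v)
    if (length(u) != 1L) stop("subject assigned to several between levels")
    u
  }, character(1))
  nw <- nlevels(w)
  ns <- nlevels(s)
  ng <- nlevels(g)
  n_per_group <- table(factor(subj_group, levels = levels(g)))
  if (any(n_per_group < 2)) stop("need >= 2 subjects per group")

  grand <- mean(y)
  subj_mean <- tapply(y, s, mean)
  group_mean <- tapply(y, g, mean)
  within_mean <- tapply(y, w, mean)
  cell_mean <- tapply(y, list(g, w), mean)

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- nw * sum((subj_mean - grand)^2)
  ss_g <- nw * sum(n_per_group * (group_mean - grand)^2)
  ss_subj_err <- ss_between_subj - ss_g
  ss_w <- sum(table(w) * (within_mean - grand)^2)
  ss_cells <- 0
  for (gi in levels(g)) for (wi in levels(w)) {
    nobs <- n_per_group[[gi]]
    ss_cells <- ss_cells + nobs *
      (cell_mean[gi, wi] - group_mean[[gi]] - within_mean[[wi]] + grand)^2
  }
  ss_gw <- ss_cells
  ss_within_err <- ss_total - ss_between_subj - ss_w - ss_gw

  df_g <- ng - 1L
  df_subj <- ns - ng
  df_w <- nw - 1L
  df_gw <- df_g * df_w
  df_werr <- df_subj * df_w

  # an effect with zero sum of squares has F = 0 even when the matching
  # error stratum is also degenerate
  safe_f <- function(ssn, dfn, sse, dfe) {
    if (ssn <= .Machine$double.eps * max(1, ss_total)) return(0)
    (ssn / dfn) / (sse / dfe)
  }
  f_g <- safe_f(ss_g, df_g, ss_subj_err, df_subj)
  f_w <- safe_f(ss_w, df_w, ss_within_err, df_werr)
  f_gw <- safe_f(ss_gw, df_gw, ss_within_err, df_werr)

  # Greenhouse–Geisser epsilon from the pooled within-group covariance of
  # subject profiles
  prof <- matrix(NA_real_, ns, nw,
                 dimnames = list(levels(s), levels(w)))
  for (i in seq_along(y)) prof[as.integer(s[i]), as.integer(w[i])] <- y[i]
  centered <- prof
  for (gi in levels(g)) {
    rows <- subj_group == gi
    centered[rows, ] <- sweep(prof[rows, , drop = FALSE], 2,
                              colMeans(prof[rows, , drop = FALSE]))
  }
  S <- crossprod(centered) / df_subj
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (nw * (dbar - sbar))^2
  den <- (nw - 1) * (sum(S^2) - 2 * nw * sum(rowMeans(S)^2) +
                       nw^2 * sbar^2)
  eps <- if (den > 0) num / den else 1
  eps <- min(1, max(1 / (nw - 1), eps))

  p_g <- stats::pf(f_g, df_g, df_subj, lower.tail = FALSE)
  p_w <- stats::pf(f_w, df_w, df_werr, lower.tail = FALSE)
  p_gw <- stats::pf(f_gw, df_gw, df_werr, lower.tail = FALSE)
  p_w_gg <- stats::pf(f_w, df_w * eps, df_werr * eps, lower.tail = FALSE)
  p_gw_gg <- stats::pf(f_gw, df_gw * eps, df_werr * eps,
                       lower.tail = FALSE)
  list(
    between = test_result(c(F = f_g), p_g, dof = c(df_g, df_subj),
                          method = "mixed ANOVA, between effect",
                          extra = list(ss = ss_g, ss_err = ss_subj_err)),
    within = test_result(c(F = f_w), p_w, dof = c(df_w, df_werr),
                         method = "mixed ANOVA, within effect",
                         extra = list(ss = ss_w, ss_err = ss_within_err,
                                      p_gg = p_w_gg, epsilon_gg = eps)),
    interaction = test_result(c(F = f_gw), p_gw, dof = c(df_gw, df_werr),
                              method = "mixed ANOVA, interaction",
                              extra = list(ss = ss_gw,
                                           ss_err = ss_within_err,
                                           p_gg = p_gw_gg,
                                           epsilon_gg = eps))
  )
}

#' Grubbs critical value
#'
#' Closed form: `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))`
#' with `t` the upper `alpha/(2n)` quantile of the t distribution on
#' `n - 2` df.
#'
#' @param n sample size, >= 3.
#' @param alpha significance level, default 0.05.
#' @return critical G.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3L)
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Grubbs outlier screen
#'
#' Tests the single most deviant observation (`G = max|x - mean| / sd`)
#' against the closed-form critical value at `alpha`; with
#' `iterate = TRUE`, flagged points are removed and the remainder
#' re-tested until no further outlier is found (at least 3 points are
#' always retained).
#'
#' @param x numeric, `n >= 3`, nonzero variance.
#' @param alpha significance level, default 0.05.
#' @param iterate re-test after removal.
#' @return list with `outliers` (indices into `x`, possibly empty), `G`
#'   and `critical` of the first pass.
#' @export
grubbs_outlier <- function(x, alpha = 0.05, iterate = FALSE) {
  stopifnot(length(x) >= 3L)
  if (stats::sd(x) == 0) stop("constant data: Grubbs test undefined")
  flag <- integer(0)
  keep <- seq_along(x)
  first <- NULL
  repeat {
    xi <- x[keep]
    if (length(xi) < 3L || stats::sd(xi) == 0) break
    dev <- abs(xi - mean(xi))
    G <- max(dev) / stats::sd(xi)
    crit <- grubbs_critical(length(xi), alpha)
    if (is.null(first)) first <- c(G = G, critical = crit)
    if (G > crit) {
      idx <- keep[which.max(dev)]
      flag <- c(flag, idx)
      keep <- setdiff(keep, idx)
      if (!iterate) break
    } else break
  }
  list(outliers = flag, G = unname(first["G"]),
       critical = unname(first["critical"]))
}
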