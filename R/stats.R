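#' Ordinary least-squares line fit
#'
#' Thin wrapper around [stats::lm()] returning slope, intercept, R-squared
#' and n. A constant response (zero total sum of squares) is a degenerate
#' case: R-squared is reported as 0 and the result flagged.
#'
#' @param x Predictor values; must not be constant.
#' @param y Response values, same length as `x`.
#' @return An object of class `us_regression`.
#' @examples
#' fit_linear(1:5, 2 * (1:5) + 1)
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("at least 3 points are required")
  if (stats::sd(x) == 0) stop("'x' is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  degenerate <- ss_tot == 0
  r2 <- if (degenerate) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n = length(x), degenerate = degenerate),
    class = "us_regression"
  )
}

#' @export
print.us_regression <- function(x, ...) {
  cat(sprintf("<us_regression> y = %.6g + %.6g x, R^2 = %.4f (n = %d)%s\n",
              x$intercept, x$slope, x$r_squared, x$n,
              if (x$degenerate) " [degenerate: constant response]" else ""))
  invisible(x)
}

#' Concentration-gradient regressions
#'
#' The study-level regressions: attenuation coefficient and speed of sound,
#' each against concentration (wt%) and against cell count, i.e. four
#' ordinary least-squares fits per strain. By default replicates are
#' collapsed to their means per concentration before fitting (matching the
#' error-bar presentation of per-concentration means); set
#' `use_replicate_means = FALSE` to fit all replicate points.
#'
#' @param estimates A data frame with columns `wt_pct`, `cells_per_ml`,
#'   `c_mps`, `alpha_npm` (one row per sample estimate), or a
#'   `gradient_experiment` from [run_gradient_experiment()].
#' @param use_replicate_means Collapse replicates to concentration means
#'   before fitting (default `TRUE`).
#' @return An object of class `gradient_regressions`: a named list of
#'   [fit_linear()] results (`alpha_vs_wt`, `alpha_vs_cells`, `c_vs_wt`,
#'   `c_vs_cells`).
#' @export
gradient_analysis <- function(estimates, use_replicate_means = TRUE) {
  if (inherits(estimates, "gradient_experiment")) {
    estimates <- estimates$estimates
  }
  need <- c("wt_pct", "cells_per_ml", "c_mps", "alpha_npm")
  if (!all(need %in% names(estimates))) {
    stop("'estimates' must have columns ", paste(need, collapse = ", "))
  }
  if (length(unique(estimates$wt_pct)) < 3L) {
    stop("at least 3 distinct concentrations are required")
  }
  df <- estimates
  if (use_replicate_means) {
    df <- stats::aggregate(df[need[-1]], by = list(wt_pct = df$wt_pct), mean)
  }
  structure(
    list(alpha_vs_wt = fit_linear(df$wt_pct, df$alpha_npm),
         alpha_vs_cells = fit_linear(df$cells_per_ml, df$alpha_npm),
         c_vs_wt = fit_linear(df$wt_pct, df$c_mps),
         c_vs_cells = fit_linear(df$cells_per_ml, df$c_mps)),
    class = "gradient_regressions"
  )
}

#' @export
print.gradient_regressions <- function(x, ...) {
  cat("<gradient_regressions>\n")
  lab <- c(alpha_vs_wt = "alpha ~ wt%%     ",
           alpha_vs_cells = "alpha ~ cells/mL",
           c_vs_wt = "c ~ wt%%        ",
           c_vs_cells = "c ~ cells/mL    ")
  for (nm in names(x)) {
    cat(sprintf(paste0("  ", lab[[nm]], ": slope = %.6g, R^2 = %.4f\n"),
                x[[nm]]$slope, x[[nm]]$r_squared))
  }
  invisible(x)
}

#' One-way ANOVA with Tukey-Kramer HSD and compact letter display
#'
#' Group comparison as performed in the study: one-way analysis of variance
#' followed by Tukey's HSD post-hoc test on all pairs (the Tukey-Kramer
#' harmonic-mean form when group sizes differ), summarized as a compact
#' letter display in which two groups share a letter if and only if their
#' adjusted p-value is at or above `alpha_level`.
#'
#' @param groups Named list of numeric vectors (one per group), each with at
#'   least 2 observations.
#' @param alpha_level Significance level (default 0.05).
#' @param normality_gate If `TRUE`, apply [shapiro_wilk_gate()] first and
#'   exclude non-normal groups with a warning (ANOVA is applied to normally
#'   distributed data only).
#' @return An object of class `us_group_comparison`: `means`, `sds`, `n`,
#'   `anova_p`, `pairwise` (data frame with `group1`, `group2`,
#'   `p_adjusted`, `significant`), `letters`, `alpha_level`.
#' @examples
#' set.seed(1)
#' anova_tukey(list(a = rnorm(5), b = rnorm(5), c = rnorm(5, 10)))
#' @export
anova_tukey <- function(groups, alpha_level = 0.05, normality_gate = FALSE) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("'groups' must be a named list of at least 2 groups")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("'groups' must be named")
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least 2 observations")
  }
  if (normality_gate) {
    gate <- shapiro_wilk_gate(groups, alpha_level = alpha_level)
    if (any(!gate$normal)) {
      warning("excluding non-normal group(s) from ANOVA: ",
              paste(gate$group[!gate$normal], collapse = ", "))
      groups <- groups[gate$normal]
      if (length(groups) < 2L) stop("fewer than 2 normal groups remain")
    }
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  fit <- stats::aov(values ~ g)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha_level)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                         diff = tk[, "diff"], p_adjusted = tk[, "p adj"],
                         row.names = NULL, stringsAsFactors = FALSE)
  pairwise$significant <- pairwise$p_adjusted < alpha_level

  letters <- compact_letter_display(names(groups), pairwise)
  structure(
    list(means = vapply(groups, mean, numeric(1)),
         sds = vapply(groups, stats::sd, numeric(1)),
         n = vapply(groups, length, integer(1)),
         anova_p = anova_p, pairwise = pairwise, letters = letters,
         alpha_level = alpha_level),
    class = "us_group_comparison"
  )
}

# Insert-and-absorb compact letter display from a pairwise significance
# table: start from one class holding all groups; for every significant
# pair, split each class containing both; absorb classes that are subsets
# of others; label classes a, b, c, ... in order of first group.
compact_letter_display <- function(group_names, pairwise) {
  classes <- list(group_names)
  sig <- pairwise[pairwise$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    g1 <- sig$group1[i]; g2 <- sig$group2[i]
    new_classes <- list()
    for (cl in classes) {
      if (g1 %in% cl && g2 %in% cl) {
        new_classes <- c(new_classes, list(setdiff(cl, g1)),
                         list(setdiff(cl, g2)))
      } else {
        new_classes <- c(new_classes, list(cl))
      }
    }
    # absorb: drop classes that are subsets (or duplicates) of a survivor
    keep <- rep(TRUE, length(new_classes))
    for (a in seq_along(new_classes)) {
      for (b in seq_along(new_classes)) {
        if (a == b || !keep[a] || !keep[b]) next
        if (all(new_classes[[a]] %in% new_classes[[b]]) &&
            (length(new_classes[[a]]) < length(new_classes[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    classes <- new_classes[keep]
  }
  # order classes by position of their first member, assign letters
  first_pos <- vapply(classes, function(cl) min(match(cl, group_names)),
                      numeric(1))
  classes <- classes[order(first_pos)]
  out <- stats::setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(classes)) {
    for (gname in classes[[i]]) {
      out[gname] <- paste0(out[gname], letters[i])
    }
  }
  out
}

#' @export
print.us_group_comparison <- function(x, ...) {
  cat(sprintf("<us_group_comparison> one-way ANOVA p = %.3g (alpha = %g)\n",
              x$anova_p, x$alpha_level))
  for (gname in names(x$means)) {
    cat(sprintf("  %-14s %10.4f +/- %.4f  (n = %d)  %s\n", gname,
                x$means[gname], x$sds[gname], x$n[gname], x$letters[gname]))
  }
  cat("  groups sharing no letter differ significantly (Tukey-Kramer HSD)\n")
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Per-group Shapiro-Wilk test; a group is flagged normal when p exceeds
#' `alpha_level` (the conventional reading of testing at that level).
#'
#' @param groups Named list of numeric vectors, each with n >= 3.
#' @param alpha_level Significance level (default 0.05).
#' @return Data frame with columns `group`, `n`, `p_value`, `normal`.
#' @export
shapiro_wilk_gate <- function(groups, alpha_level = 0.05) {
  if (!is.list(groups) || length(groups) == 0L) {
    stop("'groups' must be a non-empty named list")
  }
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 3L)) stop("Shapiro-Wilk requires at least 3 observations per group")
  p <- vapply(groups, function(v) stats::shapiro.test(v)$p.value, numeric(1))
  data.frame(group = names(groups), n = ns, p_value = p,
             normal = p > alpha_level, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Volume-weighted median particle size (x50)
#'
#' The particle size at which half of the total particle volume lies in
#' smaller particles. Computed from the binned volume-density distribution
#' by linear interpolation of the cumulative percentage against log particle
#' size within the straddling bin (the laser-diffraction convention for
#' log-spaced size grids). If all mass sits in a single bin the rule reduces
#' to the bin's geometric midpoint; this degenerate case raises a warning.
#'
#' @param psd A [particle_size_distribution()].
#' @return x50 in um.
#' @examples
#' p <- particle_size_distribution(c(4, 6), 100)
#' suppressWarnings(compute_x50(p))  # geometric midpoint, ~4.90 um
#' @export
compute_x50 <- function(psd) {
  stopifnot(inherits(psd, "psd"))
  dens <- psd$volume_density
  edges <- psd$bin_edges
  total <- sum(dens)
  cum <- c(0, cumsum(dens))
  if (max(dens) >= total * (1 - 1e-12)) {
    warning("degenerate distribution: all mass in one bin; ",
            "x50 is the bin's geometric midpoint")
  }
  i <- which(cum >= total / 2)[1] - 1L  # straddling bin
  if (i < 1L) i <- 1L
  frac <- (total / 2 - cum[i]) / dens[i]
  exp(log(edges[i]) + frac * (log(edges[i + 1]) - log(edges[i])))
}
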