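#' Statistical test report
#'
#' Light container for the outputs of the package's statistical battery:
#' test name, statistic, degrees of freedom (possibly fractional, as for
#' the Welch t), p value, optional grouping letters, and whether a
#' transform was applied upstream.
#'
#' @param test test name.
#' @param statistic test statistic.
#' @param df degrees of freedom (scalar or length-2 for F tests).
#' @param p.value two-sided p value.
#' @param groups optional named character vector of grouping letters.
#' @param transform transform applied to the data before testing, if any.
#' @return Object of class `test_report`.
#' @export
test_report <- function(test, statistic, df, p.value, groups = NULL,
                        transform = NA_character_) {
  stopifnot(p.value >= 0, p.value <= 1 + 1e-12, all(df > 0 | is.na(df)))
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p.value = min(unname(p.value), 1),
                 groups = groups, transform = transform),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test, x$statistic, dfs, x$p.value))
  if (!is.null(x$groups))
    cat("groups:", paste(names(x$groups), x$groups, sep = "=",
                         collapse = " "), "\n")
  invisible(x)
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom (hence the
#' fractional df this package reports). Two-sided.
#'
#' @param x,y numeric samples, each with n >= 2.
#' @return A `test_report`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(test_report("Welch t", 0,
                                               length(x) + length(y) - 2, 1))
    stop("both samples have zero variance")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  test_report("Welch t", tt$statistic, tt$parameter, tt$p.value)
}

#' One-way ANOVA
#'
#' Fixed-effects one-way analysis of variance with the conventional
#' degrees of freedom (k - 1, N - k).
#'
#' @param groups list of numeric samples, each with n >= 2.
#' @return A `test_report` with `df = c(k - 1, N - k)`.
#' @export
anova1 <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs n >= 2")
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(seq_along(groups), vapply(groups, length, 1L))))
  k <- length(groups)
  # constant data: aov's F is 0/0; report no evidence against the null
  # rather than the numerically unstable perfect-fit ratio
  if (diff(range(dat$value)) == 0)
    return(test_report("one-way ANOVA", 0, c(k - 1L, nrow(dat) - k), 1))
  fit <- stats::aov(value ~ group, data = dat)
  tab <- stats::anova(fit)
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (is.na(f)) { f <- 0; p <- 1 }  # zero residual AND between variance
  test_report("one-way ANOVA", f, c(tab$Df[1], tab$Df[2]), p)
}

#' Tukey HSD post-hoc comparisons with compact letter display
#'
#' All pairwise comparisons by the studentized-range criterion following a
#' one-way ANOVA, plus grouping letters: groups sharing a letter do not
#' differ at the chosen level.
#'
#' @param groups list (optionally named) of numeric samples.
#' @param alpha family-wise significance level (default 0.05).
#' @return List with `pairwise` (data frame: comparison, diff, p.adj) and
#'   `letters` (named character vector of compact letters, one per group).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = dat)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairwise <- data.frame(comparison = rownames(hsd),
                         diff = hsd[, "diff"],
                         p.adj = hsd[, "p adj"],
                         row.names = NULL, stringsAsFactors = FALSE)
  # identical groups give 0/0 studentized ranges -> NaN p; not different
  pairwise$p.adj[is.nan(pairwise$p.adj)] <- 1
  letters <- cld_letters(names(groups),
                         vapply(groups, mean, 1),
                         pairwise, alpha)
  list(pairwise = pairwise, letters = letters)
}

# Compact letter display by insert-absorb on the pairwise "not
# significantly different" relation. Groups are processed in order of
# decreasing mean, the convention of agronomy-style mean-separation tables.
cld_letters <- function(group_names, group_means, pairwise, alpha) {
  k <- length(group_names)
  differ <- matrix(FALSE, k, k, dimnames = list(group_names, group_names))
  for (r in seq_len(nrow(pairwise))) {
    nm <- strsplit(pairwise$comparison[r], "-", fixed = TRUE)[[1]]
    if (pairwise$p.adj[r] < alpha) {
      differ[nm[1], nm[2]] <- TRUE
      differ[nm[2], nm[1]] <- TRUE
    }
  }
  ord <- order(group_means, decreasing = TRUE)
  sets <- list()  # each: character vector of member groups
  for (g in group_names[ord]) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(differ[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  # absorb sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets))
    if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]]))
      keep[i] <- FALSE
  sets <- sets[keep]
  out <- stats::setNames(rep("", k), group_names)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  out[group_names]
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney-Wilcoxon test between two independent samples.
#' Exact enumeration is used when both samples are small (min n <= 10) and
#' tie-free; otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   default `NULL` applies the rule above.
#' @return A `test_report` (statistic is the Mann-Whitney U of `x`).
#' @export
wilcoxon_ranksum <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) stop("empty sample")
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- min(length(x), length(y)) <= 10L && !ties
  if (ties && all(c(x, y) == c(x, y)[1])) {
    warning("all observations tied; p = 1")
    return(test_report("Wilcoxon rank-sum", length(x) * length(y) / 2,
                       NA_real_, 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  test_report("Wilcoxon rank-sum", wt$statistic, NA_real_, wt$p.value)
}

#' Parametric-vs-nonparametric gate
#'
#' Runs the Bartlett variance-homogeneity test and per-group Shapiro-Wilk
#' normality tests at the chosen level; recommends the nonparametric branch
#' if either assumption fails. Groups too small for Shapiro-Wilk (n < 3)
#' default to nonparametric with a warning.
#'
#' @param groups list of numeric samples.
#' @param alpha level for the assumption checks (default 0.05).
#' @return List with `decision` (`"parametric"` or `"nonparametric"`),
#'   `bartlett` and `shapiro` (`test_report`s; `shapiro` is the worst-case
#'   group), and `detail` per-group Shapiro p values.
#' @export
stat_gate <- function(groups, alpha = 0.05) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, 1L) < 3L)) {
    warning("group with n < 3: Shapiro-Wilk not applicable, ",
            "defaulting to nonparametric")
    return(list(decision = "nonparametric", bartlett = NULL, shapiro = NULL,
                detail = NULL))
  }
  bt <- stats::bartlett.test(groups)
  shp <- vapply(groups, function(g) {
    if (stats::sd(g) == 0) return(0)  # degenerate: clearly non-normal
    stats::shapiro.test(g)$p.value
  }, 1)
  worst <- which.min(shp)
  decision <- if (bt$p.value < alpha || any(shp < alpha))
    "nonparametric" else "parametric"
  list(decision = decision,
       bartlett = test_report("Bartlett", bt$statistic, bt$parameter,
                              bt$p.value),
       shapiro = test_report("Shapiro-Wilk (worst group)",
                             NA_real_, NA_real_, shp[worst]),
       detail = shp)
}

#' Arcsine square-root transform for proportions
#'
#' The variance-stabilising transform asin(sqrt(x)) classically applied to
#' proportion data such as Fv/Fm before parametric testing.
#'
#' @param x numeric vector of proportions in [0, 1].
#' @return Transformed vector in [0, pi/2].
#' @export
arcsine_transform <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("arcsine transform requires values in [0, 1]")
  asin(sqrt(x))
}
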