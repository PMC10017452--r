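#' Relative treatment effects from mid-ranks
#'
#' For a longitudinal factorial table (cage x week observations with sex and
#' genotype as between-cage factors), ranks all observations jointly with
#' mid-ranks for ties and returns, per (sex, genotype, week) cell, the
#' relative treatment effect `p = (mean mid-rank - 1/2) / N`, `N` being the
#' total number of observations. Effects lie in (0, 1); 0.5 means a cell
#' whose distribution is stochastically neither larger nor smaller than the
#' pooled data. Invariant under strictly monotone transforms of the metric.
#'
#' @param data Table with columns `cage_id`, `sex`, `genotype`, `week`,
#'   `value`.
#' @return Tibble `sex, genotype, week, n, relative_effect`.
#' @export
relative_effects <- function(data) {
  check_design_cols(data)
  n_all <- nrow(data)
  data |>
    dplyr::mutate(.r = rank(.data$value)) |>
    dplyr::group_by(.data$sex, .data$genotype, .data$week) |>
    dplyr::summarise(
      n = dplyr::n(),
      relative_effect = (mean(.data$.r) - 0.5) / n_all,
      .groups = "drop"
    )
}

#' Rank-based ANOVA-type tests for a two-whole-plot-factor longitudinal design
#'
#' Fits the nonparametric ANOVA-type statistic (ATS) for a factorial
#' longitudinal layout with two between-subject (whole-plot) factors -- sex
#' and genotype -- and one within-subject (sub-plot) factor -- week -- with
#' the cage as the subject (experimental unit). All observations are jointly
#' mid-ranked; for each effect the ATS is the quadratic form of the cell mean
#' ranks in the effect's projection, scaled by the trace of the projected
#' rank covariance, and referred to an F distribution with Box-approximated
#' (possibly non-integer) numerator degrees of freedom and infinite
#' denominator degrees of freedom. Subjects must be observed in every week
#' (complete repeated measures); cage counts per group may be unbalanced.
#'
#' Single-level factors are tolerated (their effects are reported as `NA`),
#' so the same routine serves sex-stratified post-hoc layouts with genotype
#' and week only. Zero rank variance (all values identical) flags the fit as
#' degenerate with no p-values.
#'
#' @param data Table with columns `cage_id`, `sex`, `genotype`, `week`,
#'   `value`; one row per cage x week.
#' @return An object of class `cage_ats`; see [tidy.cage_ats()] and
#'   [glance.cage_ats()].
#' @examples
#' d <- tidyr::expand_grid(cage_id = sprintf("C%02d", 1:12), week = 1:3)
#' d$sex <- rep(c("M", "F"), each = 18)
#' d$genotype <- rep(rep(c("WT", "MUT"), each = 9), 2)
#' set.seed(1)
#' d$value <- rnorm(nrow(d))
#' ats_f2_ld_f1(d)
#' @export
ats_f2_ld_f1 <- function(data) {
  check_design_cols(data)
  data <- dplyr::as_tibble(data)
  data$sex <- factor(data$sex)
  data$genotype <- factor(data$genotype)
  weeks <- sort(unique(data$week))
  t_n <- length(weeks)
  a <- nlevels(data$sex)
  b <- nlevels(data$genotype)

  # complete repeated measures: every cage observed in every week
  per_cage <- dplyr::count(data, .data$cage_id)
  if (any(per_cage$n != t_n) || anyNA(data$value)) {
    stop("design error: every cage must have a value for every week", call. = FALSE)
  }
  cage_info <- dplyr::distinct(data, .data$cage_id, .data$sex, .data$genotype)
  if (nrow(cage_info) != dplyr::n_distinct(data$cage_id)) {
    stop("design error: each cage must sit in exactly one (sex, genotype) cell",
         call. = FALSE)
  }
  cells <- dplyr::count(cage_info, .data$sex, .data$genotype, .drop = FALSE)
  if (any(cells$n < 2)) {
    stop("design error: need at least 2 cages in every (sex, genotype) cell",
         call. = FALSE)
  }

  data$.r <- rank(data$value)
  n_obs <- nrow(data)
  # subject rank matrix, rows ordered by (sex, genotype, cage), cols by week
  wide <- data |>
    dplyr::arrange(.data$sex, .data$genotype, .data$cage_id,
                   match(.data$week, weeks)) |>
    dplyr::group_by(.data$sex, .data$genotype, .data$cage_id) |>
    dplyr::summarise(.rr = list(.data$.r), .groups = "drop")
  rmat <- do.call(rbind, wide$.rr)
  grp <- interaction(wide$sex, wide$genotype, lex.order = TRUE, drop = FALSE)
  grp_levels <- levels(grp)

  # cell mean ranks q (sex slowest, genotype, then week) and the block-
  # diagonal covariance of q: within group g, Cov over weeks = S_g / n_g
  d_dim <- a * b * t_n
  q <- numeric(d_dim)
  vmat <- matrix(0, d_dim, d_dim)
  degenerate <- TRUE
  for (g in seq_along(grp_levels)) {
    rows <- which(grp == grp_levels[g])
    block <- ((g - 1) * t_n + 1):(g * t_n)
    rg <- rmat[rows, , drop = FALSE]
    q[block] <- colMeans(rg)
    sg <- stats::cov(rg)
    if (any(abs(sg) > 1e-12)) degenerate <- FALSE
    vmat[block, block] <- sg / length(rows)
  }

  proj <- function(k, type) if (type == "P") diag(k) - 1 / k else matrix(1 / k, k, k)
  effect_spec <- list(
    Sex = c("P", "J", "J"), Genotype = c("J", "P", "J"), Week = c("J", "J", "P"),
    `Sex:Genotype` = c("P", "P", "J"), `Sex:Week` = c("P", "J", "P"),
    `Genotype:Week` = c("J", "P", "P"), `Sex:Genotype:Week` = c("P", "P", "P")
  )
  rows <- lapply(names(effect_spec), function(nm) {
    sp <- effect_spec[[nm]]
    tm <- proj(a, sp[1]) %x% proj(b, sp[2]) %x% proj(t_n, sp[3])
    if (all(abs(tm) < 1e-12)) {
      return(tibble::tibble(effect = nm, statistic = NA_real_, df = NA_real_,
                            p = NA_real_))
    }
    num <- drop(crossprod(q, tm %*% q))
    tb <- tm %*% vmat
    tr1 <- sum(diag(tb))
    tr2 <- sum(tb * t(tb))
    if (degenerate || tr1 < 1e-12) {
      return(tibble::tibble(effect = nm, statistic = NA_real_, df = NA_real_,
                            p = NA_real_))
    }
    fstat <- num / tr1
    df1 <- tr1^2 / tr2
    tibble::tibble(effect = nm, statistic = fstat, df = df1,
                   p = stats::pf(fstat, df1, Inf, lower.tail = FALSE))
  })
  structure(
    list(
      effects = dplyr::bind_rows(rows),
      n_cages = nrow(wide), n_weeks = t_n, n_obs = n_obs,
      cell_sizes = cells, degenerate = degenerate,
      relative_effects = relative_effects(data)
    ),
    class = "cage_ats"
  )
}

check_design_cols <- function(data) {
  need <- c("cage_id", "sex", "genotype", "week", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("design error: missing columns ", paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' @export
print.cage_ats <- function(x, ...) {
  cat(sprintf("Rank-based ANOVA-type tests (%d cages, %d weeks, %d obs)\n",
              x$n_cages, x$n_weeks, x$n_obs))
  if (x$degenerate) cat("  ** degenerate: zero rank variance, no tests **\n")
  print(as.data.frame(x$effects), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy/glance methods for ANOVA-type fits
#'
#' `tidy()` returns one row per tested effect with the ATS value, its
#' Box-approximated numerator degrees of freedom and the upper-tail p-value;
#' `glance()` returns a one-row design summary.
#'
#' @param x A `cage_ats` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cage_ats <- function(x, ...) {
  dplyr::rename(x$effects, term = "effect", p.value = "p")
}

#' @rdname tidy.cage_ats
#' @export
glance.cage_ats <- function(x, ...) {
  tibble::tibble(
    n_cages = x$n_cages, n_weeks = x$n_weeks, n_obs = x$n_obs,
    degenerate = x$degenerate
  )
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) test: exact p by full enumeration when
#' the pooled sample has at most 20 observations without ties, otherwise the
#' mid-rank normal approximation with tie correction (no continuity
#' correction). The statistic is the Mann-Whitney U of `x`.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return Tibble `statistic, p_value, method`.
#' @export
wilcoxon_two_sample <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
    auto = (length(x) + length(y)) <= 20 && !ties,
    exact = TRUE,
    normal = FALSE
  )
  if (use_exact && ties) {
    use_exact <- FALSE
    warning("ties present; falling back to the normal approximation", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE,
                       alternative = "two.sided")
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (use_exact) "exact" else "normal"
  )
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size `m` and caps at 1, preserving
#' order. `m` defaults to the number of p-values but may be larger when the
#' family includes comparisons not in `p` (e.g. all hour bins of a panel).
#'
#' @param p Numeric vector of p-values.
#' @param m Family size, at least `length(p)`.
#' @return Adjusted p-values.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 3)
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (m < length(p)) stop("m must be at least length(p)", call. = FALSE)
  pmin(1, p * m)
}
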