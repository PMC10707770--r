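# Statistical stage: arcsine transformation of percentage data, nested
# repeated-measures ANOVA with a split-plot error structure (zones nested
# within fruits), Tukey all-pairs comparisons with a compact letter display,
# and correlation checks.

#' Arcsine (angular) transformation of proportions
#'
#' `asin(sqrt(p))`, the classical variance-stabilizing transformation for
#' percentage data before ANOVA. Monotone on [0, 1]; maps 0 to 0 and 1 to
#' pi/2.
#'
#' @param p proportions in [0, 1] (divide percentages by 100 first).
#' @return transformed values in [0, pi/2].
#' @export
arcsine_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("domain error: proportions must lie in [0, 1]", call. = FALSE)
  }
  asin(sqrt(p))
}

#' Nested repeated-measures ANOVA (zones nested within fruits)
#'
#' Fits the split-plot error structure implied by zones being repeated
#' measures within fruits: treatment, stage and their interaction are tested
#' against the between-fruit stratum (fruit means), while zone and its
#' interactions with the between factors are tested against the within-fruit
#' stratum. Replicate images within a fruit x zone cell are averaged first
#' (they are subsamples, not experimental units). Sums of squares are Type
#' II, so unbalanced designs (e.g. fewer fruits at one stage) are handled by
#' a fixed convention; on balanced designs the decomposition is the exact
#' split-plot ANOVA.
#'
#' @param data data frame with columns for the response and the factors.
#' @param response name of the response column.
#' @param between between-fruit fixed factors (default treatment and stage;
#'   a single factor is allowed).
#' @param unit the experimental unit column (fruit).
#' @param within the repeated-measures factor nested in the unit (zone).
#' @param alpha significance level carried to letter displays.
#' @return a `nested_anova` object with `effects` (term, df, sum_sq,
#'   mean_sq, statistic, p_value, stratum), fruit-level and cell means, and
#'   the residual variance/df of each stratum. `tidy()` and `glance()`
#'   methods are provided.
#' @export
nested_rm_anova <- function(data, response, between = c("treatment", "stage"),
                            unit = "fruit", within = "zone", alpha = 0.05) {
  data <- as.data.frame(data)
  stopifnot(response %in% names(data), all(between %in% names(data)),
            unit %in% names(data), within %in% names(data))
  y <- data[[response]]
  if (any(!is.finite(y))) stop("response contains non-finite values", call. = FALSE)
  for (f in c(between, within)) {
    if (length(unique(data[[f]])) < 2) {
      stop("design error: factor `", f, "` has fewer than 2 levels",
           call. = FALSE)
    }
  }
  # a fruit id must be unique across treatments/stages, not just within
  data$.unit <- interaction(data[c(between, unit)], drop = TRUE)
  data$.y <- y
  for (f in c(between, within)) data[[f]] <- factor(data[[f]])
  cells_per_unit <- tapply(data$.unit, interaction(data[between], drop = TRUE),
                           function(u) length(unique(u)))
  if (any(cells_per_unit < 2)) {
    stop("design error: need at least 2 fruits per treatment cell",
         call. = FALSE)
  }

  # a constant response has no variance to decompose; fit the design on a
  # structureless surrogate response to recover df/terms, then flag every
  # test NaN
  degenerate <- all(abs(y - mean(y)) < 1e-12)
  if (degenerate) data$.y <- sin(seq_along(data$.y) * 2.39996)

  # average replicate images within fruit x zone
  cell <- stats::aggregate(
    data$.y, by = c(data[c(between, within)], list(.unit = data$.unit)),
    FUN = mean)
  names(cell)[ncol(cell)] <- ".y"
  n_zone <- length(levels(cell[[within]]))

  # between-fruit stratum: fruit means; SS scaled by the number of zones so
  # that the two strata add up to the total SS on balanced designs
  fruit <- stats::aggregate(cell$.y, by = list(.unit = cell$.unit), FUN = mean)
  names(fruit)[2] <- ".y"
  meta <- unique(cell[c(".unit", between)])
  fruit <- merge(fruit, meta, by = ".unit")
  fb <- stats::as.formula(paste(".y ~", paste(between, collapse = " * ")))
  lm_b <- stats::lm(fb, data = fruit)
  if (stats::df.residual(lm_b) < 1) {
    stop("rank error: zero residual degrees of freedom in the between-fruit ",
         "stratum", call. = FALSE)
  }
  ss_b <- suppressMessages(car::Anova(lm_b, type = 2, singular.ok = TRUE))
  between_tab <- data.frame(
    term = rownames(ss_b), sum_sq = ss_b$`Sum Sq` * n_zone, df = ss_b$Df,
    stratum = "between-fruit", stringsAsFactors = FALSE
  )
  resid_row_b <- between_tab$term == "Residuals"
  between_tab$term[resid_row_b] <- "fruit(between residual)"

  # within-fruit stratum: fruit absorbed as a block; zone and its
  # interactions with the between factors tested against the residual
  fw <- stats::as.formula(paste(
    ".y ~ .unit +", within, "+",
    paste(vapply(between, function(b) paste0(within, ":", b), ""),
          collapse = " + "),
    if (length(between) > 1) paste0(" + ", within, ":",
                                    paste(between, collapse = ":")) else ""
  ))
  lm_w <- stats::lm(fw, data = cell)
  # the .unit block absorbs the between factors, so car reports aliasing;
  # that is the intended split-plot structure
  ss_w <- suppressMessages(
    suppressWarnings(car::Anova(lm_w, type = 2, singular.ok = TRUE)))
  within_tab <- data.frame(
    term = rownames(ss_w), sum_sq = ss_w$`Sum Sq`, df = ss_w$Df,
    stratum = "within-fruit", stringsAsFactors = FALSE
  )
  within_tab <- within_tab[within_tab$term != ".unit", ]
  within_tab$term[within_tab$term == "Residuals"] <- "within residual"

  tab <- rbind(between_tab, within_tab)
  tab$mean_sq <- tab$sum_sq / tab$df
  ms_err_b <- tab$mean_sq[tab$term == "fruit(between residual)"]
  df_err_b <- tab$df[tab$term == "fruit(between residual)"]
  ms_err_w <- tab$mean_sq[tab$term == "within residual"]
  df_err_w <- tab$df[tab$term == "within residual"]
  if (df_err_w < 1) {
    stop("rank error: zero residual degrees of freedom in the within-fruit ",
         "stratum", call. = FALSE)
  }
  is_err <- tab$term %in% c("fruit(between residual)", "within residual")
  err_ms <- ifelse(tab$stratum == "between-fruit", ms_err_b, ms_err_w)
  err_df <- ifelse(tab$stratum == "between-fruit", df_err_b, df_err_w)
  tab$statistic <- ifelse(is_err, NA, tab$mean_sq / err_ms)
  tab$p_value <- ifelse(is_err, NA,
                        stats::pf(tab$statistic, tab$df, err_df,
                                  lower.tail = FALSE))
  if (degenerate) {
    tab$sum_sq <- 0; tab$mean_sq <- 0
    tab$statistic[!is_err] <- NaN
    tab$p_value[!is_err] <- NaN
    ms_err_b <- ms_err_w <- 0
  }

  structure(list(
    effects = tibble::as_tibble(tab[c("term", "stratum", "df", "sum_sq",
                                      "mean_sq", "statistic", "p_value")]),
    cell_means = tibble::as_tibble(cell),
    fruit_means = tibble::as_tibble(fruit),
    strata = list(
      between = list(ms = ms_err_b, df = df_err_b),
      within = list(ms = ms_err_w, df = df_err_w)
    ),
    response = response, between = between, within = within,
    n_zone = n_zone, alpha = alpha, degenerate = degenerate
  ), class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat("Nested repeated-measures ANOVA (", x$within, " within fruits)\n",
      sep = "")
  if (x$degenerate) cat("  [degenerate: response has no variance]\n")
  print(as.data.frame(x$effects), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname nested_rm_anova
#' @param x a `nested_anova` object.
#' @param ... unused.
#' @export
tidy.nested_anova <- function(x, ...) x$effects

#' @rdname nested_rm_anova
#' @export
glance.nested_anova <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x$fruit_means),
    n_cells = nrow(x$cell_means),
    ms_between = x$strata$between$ms, df_between = x$strata$between$df,
    ms_within = x$strata$within$ms, df_within = x$strata$within$df,
    degenerate = x$degenerate
  )
}

#' Tukey HSD comparisons with a compact letter display
#'
#' All-pairs honest-significant-difference tests via the studentized range
#' (Tukey-Kramer for unequal group sizes), followed by a compact letter
#' display in which two groups share a letter if and only if they are not
#' significantly different at `alpha`. Letters are the maximal cliques of
#' the non-significance graph, ordered by group mean, so the display encodes
#' the significant-pair matrix exactly.
#'
#' @param means named numeric vector of group means.
#' @param n group sizes (scalar or named vector).
#' @param ms_error error mean square of the appropriate ANOVA stratum.
#' @param df_error its degrees of freedom.
#' @param alpha significance level (default 0.05).
#' @return a `tukey_letters` tibble: `group`, `mean`, `n`, `letters`; the
#'   logical significance matrix is attached as attribute `"significant"`.
#' @export
tukey_letters <- function(means, n, ms_error, df_error, alpha = 0.05) {
  k <- length(means)
  stopifnot(k >= 2)
  if (!is.finite(ms_error) || ms_error <= 0) {
    stop("validation error: error mean square must be positive", call. = FALSE)
  }
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  means <- stats::setNames(as.numeric(means), names(means))
  if (length(n) == 1) n <- rep(n, k)
  if (!is.null(names(n))) n <- n[names(means)]
  if (length(n) != k || any(!is.finite(n)) || any(n <= 0)) {
    stop("validation error: group sizes must be positive and match the means",
         call. = FALSE)
  }
  qcrit <- stats::qtukey(1 - alpha, k, df_error)
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(ms_error / 2 * (1 / n[i] + 1 / n[j]))
      sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > qcrit * se
    }
  }
  # letters: maximal cliques of the non-significance graph
  nsd <- !sig; diag(nsd) <- TRUE
  gr <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected",
                                            diag = FALSE)
  cliques <- igraph::max_cliques(gr)
  cl_means <- vapply(cliques, function(cl) min(means[as.integer(cl)]), 0)
  cliques <- cliques[order(cl_means)]
  letter_of <- letters[seq_along(cliques)]
  assigned <- vapply(seq_len(k), function(i) {
    paste0(letter_of[vapply(cliques, function(cl) i %in% as.integer(cl),
                            TRUE)], collapse = "")
  }, "")
  out <- tibble::tibble(group = names(means), mean = unname(means),
                        n = unname(n), letters = assigned)
  out <- out[order(-out$mean), ]
  structure(out, significant = sig, class = c("tukey_letters", class(out)))
}

#' Squared Pearson correlation
#'
#' @param x,y paired numeric vectors (at least 3 finite pairs).
#' @return R-squared of `y` against `x`.
#' @export
r_squared <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite values", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    stop("degenerate input: constant series", call. = FALSE)
  }
  stats::cor(x, y)^2
}
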