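#' RCB ANOVA with expected-mean-squares F tests
#'
#' Fits the randomized-complete-block movement model
#' `response ~ Cultivar + PlantingDate + Pos(PlantingDate) +
#' Cultivar:PlantingDate + Cultivar:Pos(PlantingDate)` with sequential
#' (model-order) sums of squares, then forms F ratios whose denominators are
#' chosen from the expected mean squares so each ratio isolates the tested
#' component:
#' Cultivar and Cultivar x PlantingDate are tested against
#' Cultivar x Pos(PlantingDate); PlantingDate against Pos(PlantingDate);
#' the two position terms against the residual.
#'
#' @param data Tibble with factor columns `cultivar`, `planting_date`,
#'   `position` (inner/outer), and the response.
#' @param response Name of the response column (e.g. `"mean_freq"` or an
#'   amplitude-bin column such as `"bin_1.1_1.3"`).
#' @return An object of class `ems_anova` with a `table` tibble
#'   (`source`, `df`, `ss`, `ms`, `f`, `p`), the underlying `lm` fit, and
#'   metadata. `f`/`p` are `NA` where the response has no variation.
#' @export
anova_ems <- function(data, response) {
  for (v in c("cultivar", "planting_date", "position", response)) {
    if (!v %in% names(data)) abort(sprintf("column '%s' missing from data", v))
  }
  df <- as.data.frame(data)
  df$cultivar <- factor(df$cultivar)
  df$planting_date <- factor(df$planting_date)
  df$position <- factor(df$position)
  for (v in c("cultivar", "planting_date", "position")) {
    if (nlevels(df[[v]]) < 2) abort(sprintf("factor '%s' needs >= 2 levels", v))
  }
  df$.y <- df[[response]]
  if (any(!is.finite(df$.y))) abort("response contains non-finite values")
  fit <- lm(.y ~ cultivar + planting_date + planting_date:position +
              cultivar:planting_date + cultivar:planting_date:position,
            data = df)
  a <- withCallingHandlers(
    anova(fit),
    warning = function(w) {
      # a zero-variation response is handled downstream (F reported as NA)
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  src_map <- c("cultivar" = "Cultivar",
               "planting_date" = "PlantingDate",
               "planting_date:position" = "Pos(PlantingDate)",
               "cultivar:planting_date" = "Cultivar:PlantingDate",
               "cultivar:planting_date:position" = "Cultivar:Pos(PlantingDate)",
               "Residuals" = "Residuals")
  tab <- tibble(source = unname(src_map[rownames(a)]),
                df = a$Df, ss = a$`Sum Sq`, ms = a$`Mean Sq`)
  tab <- tab[match(src_map, tab$source), ]
  denom_of <- c("Cultivar" = "Cultivar:Pos(PlantingDate)",
                "PlantingDate" = "Pos(PlantingDate)",
                "Pos(PlantingDate)" = "Residuals",
                "Cultivar:PlantingDate" = "Cultivar:Pos(PlantingDate)",
                "Cultivar:Pos(PlantingDate)" = "Residuals")
  fval <- pval <- rep(NA_real_, nrow(tab))
  for (i in seq_len(nrow(tab) - 1)) {
    dsrc <- denom_of[[tab$source[i]]]
    j <- match(dsrc, tab$source)
    if (tab$df[j] == 0) {
      abort(sprintf("denominator '%s' for '%s' has 0 df (aliased term)",
                    dsrc, tab$source[i]))
    }
    if (tab$ms[j] > 0) {
      fval[i] <- tab$ms[i] / tab$ms[j]
      pval[i] <- pf(fval[i], tab$df[i], tab$df[j], lower.tail = FALSE)
    }
  }
  tab$f <- fval
  tab$p <- pval
  structure(list(table = tab, fit = fit, response = response,
                 denom_of = denom_of, data = df),
            class = "ems_anova")
}

#' @export
print.ems_anova <- function(x, ...) {
  cat(sprintf("EMS ANOVA for '%s'\n", x$response))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy ems_anova
#' @export
tidy.ems_anova <- function(x, ...) {
  dplyr::rename(x$table, term = "source", sumsq = "ss", meansq = "ms",
                statistic = "f", p.value = "p")
}

#' @method glance ems_anova
#' @export
glance.ems_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         df.residual = x$fit$df.residual, nobs = nrow(x$data))
}

# EMS denominator appropriate to a factor's LSD comparisons
lsd_denominator <- function(anova, factor) {
  src <- switch(factor,
                cultivar = "Cultivar:Pos(PlantingDate)",
                planting_date = "Pos(PlantingDate)",
                position = "Residuals",
                "Residuals")
  tab <- anova$table
  j <- match(src, tab$source)
  list(ms = tab$ms[j], df = tab$df[j])
}

#' LSD mean separation with multiplicity correction
#'
#' Pairwise least-significant-difference comparisons of factor-level means,
#' using the mean square that the expected-mean-squares table designates as
#' that factor's error term. P values are adjusted (`fdr` by default, as
#' used for the movement responses; `bonferroni` for the demarcation
#' agreement protocol), and levels are labelled with a compact letter
#' display: levels sharing a letter are not significantly different at
#' `alpha`.
#'
#' @param anova An `ems_anova` fit.
#' @param factor One of `"cultivar"`, `"planting_date"`, `"position"`.
#' @param alpha Significance level.
#' @param correction P-value adjustment: `"fdr"`, `"bonferroni"`, `"none"`.
#' @return An object of class `mean_separation`: tibble `means`
#'   (`level`, `mean`, `n`, `letters`) plus the pairwise table.
#' @export
lsd_mean_separation <- function(anova, factor = "cultivar", alpha = 0.05,
                                correction = c("fdr", "bonferroni", "none")) {
  correction <- match.arg(correction)
  if (!factor %in% names(anova$data)) abort(sprintf("unknown factor '%s'", factor))
  f <- factor(anova$data[[factor]])
  if (nlevels(f) < 2) abort(sprintf("factor '%s' has a single level", factor))
  y <- anova$data$.y
  means <- tapply(y, f, mean)
  ns <- tapply(y, f, length)
  den <- lsd_denominator(anova, factor)
  lev <- names(means)
  pairs <- utils::combn(lev, 2)
  pt_raw <- apply(pairs, 2, function(pr) {
    se <- sqrt(den$ms * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    tstat <- (means[[pr[1]]] - means[[pr[2]]]) / se
    2 * pt(-abs(tstat), den$df)
  })
  p_adj <- p.adjust(pt_raw, method = if (correction == "fdr") "BH" else correction)
  pw <- tibble(level1 = pairs[1, ], level2 = pairs[2, ],
               diff = means[pairs[1, ]] - means[pairs[2, ]],
               p.value = pt_raw, p.adj = p_adj,
               significant = p_adj < alpha)
  letters_tbl <- compact_letters(lev, means, pw, alpha)
  letters_tbl$n <- as.integer(ns[letters_tbl$level])
  out <- structure(list(
    means = letters_tbl, pairwise = pw, factor = factor,
    alpha = alpha, correction = correction,
    denominator = den), class = "mean_separation")
  out
}

# compact letter display: order levels by descending mean (name-ordered on
# ties), sweep out maximal runs of mutually non-significant levels, letter
# each maximal run.
compact_letters <- function(levels, means, pairwise, alpha) {
  ord <- order(-unlist(means[levels]), levels)
  lev <- levels[ord]
  k <- length(lev)
  ns <- matrix(TRUE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(nrow(pairwise))) {
    if (isTRUE(pairwise$significant[i])) {
      ns[pairwise$level1[i], pairwise$level2[i]] <- FALSE
      ns[pairwise$level2[i], pairwise$level1[i]] <- FALSE
    }
  }
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(ns[lev[i:(j + 1)], lev[i:(j + 1)]])) j <- j + 1
    grp <- lev[i:j]
    covered <- any(vapply(groups, function(g) all(grp %in% g), TRUE))
    if (!covered) groups[[length(groups) + 1]] <- grp
  }
  lab <- setNames(rep("", k), lev)
  for (g in seq_along(groups)) {
    lab[groups[[g]]] <- paste0(lab[groups[[g]]], letters[g])
  }
  tibble(level = lev, mean = as.numeric(unlist(means[lev])),
         n = NA_integer_, letters = unname(lab))
}

#' @export
print.mean_separation <- function(x, ...) {
  cat(sprintf("LSD mean separation for '%s' (alpha = %g, %s correction)\n",
              x$factor, x$alpha, x$correction))
  print(as.data.frame(x$means), digits = 4)
  invisible(x)
}

#' @method tidy mean_separation
#' @export
tidy.mean_separation <- function(x, ...) x$means

#' Manual-vs-automatic demarcation agreement
#'
#' For each plot, correlates the panel-normalized waveform extracted from a
#' manually demarcated region with the one from the automatic demarcation
#' (Pearson, over frames), then tests whether mean correlation differs
#' between inner and outer replicate positions with a position-only linear
#' model and an LSD comparison under Bonferroni correction.
#'
#' @param manual,auto `waveform_tbl` objects (or long tibbles with `frame`,
#'   `plot`, `value`) covering the same plots and frames.
#' @param positions Tibble with `plot` and `position` (inner/outer) columns.
#' @param alpha Significance level.
#' @return A list of class `demarcation_agreement`: `per_plot` (plot,
#'   position, r), `group_means` (position means with letters), `p.value`
#'   for the position contrast, and the `lm` fit.
#' @export
demarcation_agreement <- function(manual, auto, positions, alpha = 0.05) {
  m <- as_tibble(manual); a <- as_tibble(auto)
  plots <- unique(m$plot)
  if (!setequal(plots, unique(a$plot))) {
    abort("manual and automatic waveforms cover different plots")
  }
  rs <- vapply(plots, function(p) {
    wm <- m$value[m$plot == p]
    wa <- a$value[a$plot == p]
    if (length(wm) != length(wa)) {
      abort(sprintf("frame counts differ for plot '%s'", p))
    }
    cor(wm, wa)
  }, 0)
  per_plot <- left_join(tibble(plot = plots, r = unname(rs)), as_tibble(positions),
                        by = "plot")
  if (any(is.na(per_plot$position))) abort("position missing for some plots")
  fit <- lm(r ~ position, data = per_plot)
  means <- tapply(per_plot$r, per_plot$position, mean)
  ns <- tapply(per_plot$r, per_plot$position, length)
  mse <- sum(fit$residuals^2) / fit$df.residual
  lev <- names(means)
  pairs <- utils::combn(lev, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    2 * pt(-abs((means[[pr[1]]] - means[[pr[2]]]) / se), fit$df.residual)
  })
  p_adj <- p.adjust(p_raw, method = "bonferroni")
  pw <- tibble(level1 = pairs[1, ], level2 = pairs[2, ],
               diff = means[pairs[1, ]] - means[pairs[2, ]],
               p.value = p_raw, p.adj = p_adj, significant = p_adj < alpha)
  gm <- compact_letters(lev, means, pw, alpha)
  gm$n <- as.integer(ns[gm$level])
  structure(list(per_plot = per_plot, group_means = gm,
                 p.value = p_adj[1], fit = fit), class = "demarcation_agreement")
}

#' @export
print.demarcation_agreement <- function(x, ...) {
  cat("Demarcation agreement (manual vs automatic waveforms)\n")
  print(as.data.frame(x$group_means), digits = 3)
  cat(sprintf("position contrast p (Bonferroni) = %.4g\n", x$p.value))
  invisible(x)
}

#' @method tidy demarcation_agreement
#' @export
tidy.demarcation_agreement <- function(x, ...) x$per_plot
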