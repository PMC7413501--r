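#' Replicate summary: n, mean, SEM
#'
#' @param values Numeric vector of a per-well metric (e.g. mu_max) across
#'   replicates; \code{NA}s are dropped.
#' @return List with \code{n}, \code{mean} and \code{sem} (sample standard
#'   deviation over \code{sqrt(n)}).
#' @examples
#' summarizeReplicates(c(1, 2, 3, 4, 5))  # mean 3, sem 0.7071
#' @export
summarizeReplicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stopInsufficient("need at least 2 replicates for mean and SEM")
  list(n = n, mean = mean(values), sem = stats::sd(values) / sqrt(n))
}

checkGroups <- function(groups) {
  if (length(groups) < 2)
    stopParam("need at least 2 groups")
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(vapply(groups, length, 0L) < 2))
    stopInsufficient("every group needs at least 2 values")
  if (all(vapply(groups, stats::var, 0) == 0))
    stopDegenerate("all groups are constant: within-group variance is zero")
  groups
}

#' One-way fixed-effects ANOVA across groups
#'
#' Classical one-way ANOVA comparing a growth metric for the same strain on
#' different carbon sources (or any grouping). Thin wrapper around
#' \code{\link[stats]{aov}} that returns the quantities the downstream LSD
#' comparisons need.
#'
#' @param groups List of numeric vectors, one per group (each with >= 2
#'   values; at least one group must have positive variance).
#' @return List with \code{F}, \code{p}, \code{mse} (within-group mean
#'   square) and \code{dfError}.
#' @export
oneWayAnova <- function(groups) {
  groups <- checkGroups(groups)
  val <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(val ~ grp)
  tab <- summary(fit)[[1]]
  list(F = tab["grp", "F value"], p = tab["grp", "Pr(>F)"],
       mse = tab["Residuals", "Mean Sq"], dfError = tab["Residuals", "Df"])
}

# Compact letter display by insert-and-absorb: groups are given in ascending
# mean order; sig[i, j] = TRUE means groups i and j differ. Returns one
# letter string per group, 'a' containing the lowest-mean group. Two groups
# share a letter iff their pairwise test is non-significant.
compactLetters <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      if (all(c(i, j) %in% cols[[ci]])) {
        a <- setdiff(cols[[ci]], i)
        b <- setdiff(cols[[ci]], j)
        cols[[ci]] <- a
        cols[[length(cols) + 1]] <- b
      }
    }
    # absorb: drop any column that is a subset of another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[cj] &&
          all(cols[[ci]] %in% cols[[cj]]) && !all(cols[[cj]] %in% cols[[ci]]))
        keep[ci] <- FALSE
    }
    cols <- cols[keep]
    cols <- cols[!duplicated(lapply(cols, sort))]
  }
  # letter order: 'a' goes to the column containing the lowest-mean groups
  ord <- order(vapply(cols, min, 0L))
  cols <- cols[ord]
  letters_out <- rep("", k)
  for (ci in seq_along(cols))
    for (g in cols[[ci]])
      letters_out[g] <- paste0(letters_out[g], letters[ci])
  letters_out
}

#' Protected Fisher LSD comparisons with a compact letter display
#'
#' Implements the multiple-range comparison used for strain-by-substrate
#' growth tables: a one-way ANOVA gate followed, only when the ANOVA is
#' significant at \code{alpha}, by all pairwise least-significant-difference
#' tests
#' \deqn{|m_i - m_j| > t_{1-\alpha/2, df_e} \sqrt{MSE (1/n_i + 1/n_j)}}
#' (the unbalanced form, since replicate counts of 3--6 are common).
#' Letters are assigned by insert-and-absorb so that two groups share a
#' letter if and only if they do not differ significantly; \code{"a"} marks
#' the lowest-mean group (by convention the no-added-carbon controls).
#' When the ANOVA gate fails, all groups share \code{"a"}.
#'
#' @param groups Named list of numeric replicate vectors.
#' @param alpha Significance level (default 0.05).
#' @return A [GrowthComparison-class]; its \code{groups} table is ordered by
#'   ascending mean.
#' @examples
#' g <- list(noC = c(0.010, 0.012, 0.011),
#'           glc = c(0.070, 0.071, 0.069),
#'           xyl = c(0.050, 0.051, 0.049))
#' fisherLsdLetters(g)
#' @export
fisherLsdLetters <- function(groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stopParam("alpha must be in (0, 1)")
  groups <- checkGroups(groups)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  av <- oneWayAnova(groups)
  means <- vapply(groups, mean, 0)
  ord <- order(means)
  groups <- groups[ord]
  means <- means[ord]
  ns <- lengths(groups)
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(names(groups), names(groups)))
  if (av$p < alpha) {
    tcrit <- stats::qt(1 - alpha / 2, av$dfError)
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      lsd <- tcrit * sqrt(av$mse * (1 / ns[i] + 1 / ns[j]))
      sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > lsd
    }
  }
  lett <- compactLetters(sig)
  gt <- data.frame(
    group = names(groups), n = as.integer(ns), mean = unname(means),
    sem = vapply(groups, function(v) stats::sd(v) / sqrt(length(v)), 0),
    letters = lett, stringsAsFactors = FALSE, row.names = NULL
  )
  methods::new("GrowthComparison", groups = gt, anovaF = av$F, anovaP = av$p,
               mse = av$mse, dfError = av$dfError, alpha = alpha,
               pairwise = sig)
}

setMethod("show", "GrowthComparison", function(object) {
  cat(sprintf("GrowthComparison: %d groups, ANOVA F = %.3g (p = %.3g), alpha = %g\n",
              nrow(object@groups), object@anovaF, object@anovaP, object@alpha))
  print(object@groups, row.names = FALSE)
  invisible(NULL)
})

#' Two-sample Student t comparison between cultivation systems
#'
#' Equal-variance two-sided t test, used to compare the specific growth rate
#' of a strain on one substrate between the two cultivation systems.
#'
#' @param a,b Numeric replicate vectors (each >= 2 values).
#' @param alpha Significance level (default 0.05).
#' @return List with \code{t}, \code{df}, \code{p} and \code{significant}.
#' @examples
#' studentTCompare(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0213
#' @export
studentTCompare <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stopInsufficient("both samples need at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1, significant = FALSE))
    stopDegenerate("pooled variance is zero but means differ")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha)
}

#' Build strain-by-substrate summary tables
#'
#' Aggregates per-well kinetics into the standard publication layout: one
#' row per strain and cultivation system, one column per substrate, each
#' cell \code{"mean +/- sem^letters"} where letters come from protected
#' Fisher LSD comparisons across substrates within the strain-system row,
#' and a significance mark (\code{*}) where the same strain and substrate
#' differs between the two systems by a Student t test. Wells whose kinetics
#' failed are excluded listwise, with counts reported.
#'
#' @param results Per-well results from [analyzePlate()] with annotation
#'   columns present.
#' @param metric \code{"mu_max"} or \code{"max_od"}.
#' @param alpha Significance level (default 0.05).
#' @param digits Display rounding for means and SEMs (default 2, matching
#'   the conventional tables; the numeric columns keep full precision).
#' @return List with \code{table} (wide display \code{data.frame}),
#'   \code{cells} (long \code{data.frame} with numeric mean, sem, n,
#'   letters, cross-system flag) and \code{excluded} (failed-well count).
#' @export
groupTables <- function(results, metric = c("mu_max", "max_od"),
                        alpha = 0.05, digits = 2) {
  metric <- match.arg(metric)
  need <- c("strain", "substrate", "system", metric, "ok")
  if (!all(need %in% names(results)))
    stopParam("results must carry annotation columns (strain, substrate, system)")
  excluded <- sum(!results$ok)
  res <- results[results$ok & !is.na(results[[metric]]), , drop = FALSE]
  subs <- intersect(substrateLevels(), unique(res$substrate))
  cells <- NULL
  for (st in unique(res$strain)) for (sys in unique(res$system[res$strain == st])) {
    sel <- res[res$strain == st & res$system == sys, , drop = FALSE]
    grp <- split(sel[[metric]], factor(sel$substrate, levels = subs))
    grp <- grp[lengths(grp) > 0]
    lett <- NULL
    if (length(grp) >= 2 && !all(vapply(grp, stats::var, 0) == 0)) {
      cmp <- fisherLsdLetters(grp, alpha = alpha)
      lett <- stats::setNames(cmp@groups$letters, cmp@groups$group)
    }
    for (sb in names(grp)) {
      v <- grp[[sb]]
      cells <- rbind(cells, data.frame(
        strain = st, system = sys, substrate = sb, n = length(v),
        mean = mean(v),
        sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        letters = if (is.null(lett)) "a" else unname(lett[sb]),
        stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(cells))
    stopInsufficient("no successful wells to tabulate")

  # cross-system t tests per strain x substrate
  cells$cross_system_sig <- FALSE
  for (st in unique(cells$strain)) for (sb in unique(cells$substrate)) {
    va <- res[[metric]][res$strain == st & res$substrate == sb & res$system == "BSC"]
    vb <- res[[metric]][res$strain == st & res$substrate == sb & res$system == "Cph"]
    if (length(va) >= 2 && length(vb) >= 2 &&
        (stats::var(va) > 0 || stats::var(vb) > 0 || mean(va) == mean(vb))) {
      tt <- studentTCompare(va, vb, alpha = alpha)
      hit <- cells$strain == st & cells$substrate == sb
      cells$cross_system_sig[hit] <- tt$significant
    }
  }

  fmtCell <- function(m, s, l, x) {
    paste0(formatC(m, format = "f", digits = digits), " ± ",
           formatC(s, format = "f", digits = digits), "^", l, "^",
           ifelse(x, " *", ""))
  }
  wide <- unique(cells[, c("strain", "system")])
  for (sb in subs) wide[[sb]] <- NA_character_
  for (r in seq_len(nrow(cells))) {
    i <- which(wide$strain == cells$strain[r] & wide$system == cells$system[r])
    wide[i, cells$substrate[r]] <- fmtCell(cells$mean[r], cells$sem[r],
                                           cells$letters[r],
                                           cells$cross_system_sig[r])
  }
  rownames(wide) <- NULL
  list(table = wide, cells = cells, excluded = excluded)
}

#' Write a summary table as CSV or markdown
#'
#' @param tbl Result of [groupTables()].
#' @param sink Path or connection.
#' @param format \code{"csv"} (full-precision long table plus display table)
#'   or \code{"markdown"} (aligned display table).
#' @return Invisibly, \code{sink}.
#' @export
writeGroupTable <- function(tbl, sink, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(tbl$cells, sink, row.names = FALSE, na = "")
  } else {
    w <- tbl$table
    hdr <- paste0("| ", paste(names(w), collapse = " | "), " |")
    bar <- paste0("|", paste(rep("---", ncol(w)), collapse = "|"), "|")
    rows <- apply(w, 1L, function(r)
      paste0("| ", paste(ifelse(is.na(r), "", r), collapse = " | "), " |"))
    writeLines(c(hdr, bar, rows), con = sink)
  }
  invisible(sink)
}
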