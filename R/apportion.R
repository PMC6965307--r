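#' Pearson correlation with significance
#'
#' Sample Pearson correlation and its two-sided p-value from the usual
#' t-transform with `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return List with elements `r`, `p` and `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y lengths differ")
  if (length(x) < 3) stop_config("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop_config("undefined correlation: constant sequence")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation-based source apportionment of exposure risk
#'
#' For every demographic group and each single source category, the
#' Pearson correlation between that source's relative-risk surface and
#' the combined-source relative-risk surface, computed over the cells
#' inhabited by the group.  The source with the larger correlation is
#' flagged as the group's dominant contributor.  A group whose usable
#' cells are too few or whose risk is constant yields an `NA` row with a
#' status note; other groups are unaffected.
#'
#' @param risk A [risk_stack()].
#' @param pop A [dasymetric_map()] result, used to restrict each group's
#'   correlation to its inhabited cells.
#' @param groups Demographic groups (default all 7).
#' @param sources Single-source categories (default industrial, vehicle).
#' @param against `"group"` correlates a group's single-source risk with
#'   the same group's combined risk (the default reading);
#'   `"total"` correlates against the total-population combined risk.
#' @return Data.frame of class `apportionment_table` with columns
#'   `group`, `source`, `pearson_r`, `p_value`, `n_cells`, `status`, and
#'   a `dominant` attribute naming each group's larger-r source.
#' @export
apportion_risks <- function(risk, pop, groups = DEMO_GROUPS,
                            sources = c("industrial", "vehicle"),
                            against = c("group", "total")) {
  against <- match.arg(against)
  rows <- list()
  for (g in groups) {
    inhabited <- as.vector(pop[[g]]$values) > 0
    comb_group <- if (against == "group") g else "total"
    comb <- as.vector(risk_layer(risk, "combined", comb_group)$values)
    for (s in sources) {
      single <- as.vector(risk_layer(risk, s, g)$values)
      use <- inhabited & is.finite(single) & is.finite(comb)
      res <- tryCatch({
        if (sum(use) < 3) stop_config("fewer than 3 usable cells")
        pr <- pearson(single[use], comb[use])
        data.frame(group = g, source = s, pearson_r = pr$r, p_value = pr$p,
                   n_cells = pr$n, status = "ok")
      }, error = function(e) {
        data.frame(group = g, source = s, pearson_r = NA_real_,
                   p_value = NA_real_, n_cells = sum(use),
                   status = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  dom <- vapply(unique(out$group), function(g) {
    sub <- out[out$group == g & !is.na(out$pearson_r), ]
    if (!nrow(sub)) NA_character_ else sub$source[which.max(sub$pearson_r)]
  }, "")
  attr(out, "dominant") <- dom
  class(out) <- c("apportionment_table", "data.frame")
  out
}

#' @rdname apportion_risks
#' @param table An `apportionment_table`.
#' @param path Tab-separated output path.
#' @export
write_apportionment <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
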