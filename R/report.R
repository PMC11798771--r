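#' Fixed-effects summary table with time ratios
#'
#' Posterior mean, sd, central 95% credible interval and Weibull time
#' ratio (`exp` of the posterior mean, computed at full precision before
#' any rounding) for the intercept and every coefficient.
#'
#' @param samples an `icar_samples` object.
#' @param labels optional replacement labels for the coefficients (not the
#'   intercept); length must equal the number of coefficients.
#' @return data.frame of class `fixed_effects_table` with columns `label`,
#'   `mean`, `sd`, `lower`, `upper`, `time_ratio` (the intercept row has
#'   `NA` time ratio, as a baseline it is not a ratio).
#' @export
fixed_effects_table <- function(samples, labels = NULL) {
  stopifnot(inherits(samples, "icar_samples"))
  p <- ncol(samples$beta)
  if (!is.null(labels) && length(labels) != p)
    stop("labels has length ", length(labels), " but there are ", p,
         " coefficients")
  if (is.null(labels)) labels <- colnames(samples$beta)
  draws <- cbind(`(Intercept)` = samples$intercept, samples$beta)
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  mn <- colMeans(draws)
  out <- data.frame(
    label = c("(Intercept)", labels),
    mean = mn,
    sd = apply(draws, 2, stats::sd),
    lower = qs[1, ], upper = qs[2, ],
    time_ratio = c(NA, time_ratio(mn[-1])),
    row.names = NULL)
  class(out) <- c("fixed_effects_table", "data.frame")
  out
}

#' @export
print.fixed_effects_table <- function(x, digits = 3, ...) {
  cat("Fixed effects (posterior means and Weibull time ratios)\n")
  df <- data.frame(
    Effect = x$label,
    `Posterior mean` = formatC(x$mean, format = "f", digits = digits),
    SD = formatC(x$sd, format = "f", digits = digits),
    `95% CI` = sprintf("[%.3f, %.3f]", x$lower, x$upper),
    `Time ratio` = ifelse(is.na(x$time_ratio), "",
                          formatC(x$time_ratio, format = "f", digits = 2)),
    check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fixed_effects_table <- function(x, ...) {
  tr <- x$time_ratio[-1]
  graphics::barplot(tr - 1, names.arg = x$label[-1], horiz = TRUE, las = 1,
                    offset = 1, xlim = range(c(0.9, tr)) * c(0.95, 1.05),
                    xlab = "Weibull time ratio",
                    main = "Covariate time ratios (TR > 1 delays the event)",
                    ...)
  graphics::abline(v = 1, lty = 2)
  invisible(x)
}

#' Descriptive cross-tabulation by event status
#'
#' Counts and within-column percentages of a coded covariate by event
#' status (censored vs event), the layout of a DHS-style descriptive
#' table.
#'
#' @param dataset a [survival_data] or a data.frame with an `event` column.
#' @param factor name of the factor column.
#' @return data.frame of class `status_crosstab` with per-level counts and
#'   column percentages (`censored_n`, `censored_pct`, `event_n`,
#'   `event_pct`); percentages sum to 100 per column up to rounding.
#' @export
status_crosstab <- function(dataset, factor) {
  df <- if (inherits(dataset, "survival_data")) dataset$data else dataset
  if (!factor %in% names(df)) stop("unknown factor: ", factor)
  if (!"event" %in% names(df)) stop("dataset has no event column")
  f <- as.factor(df[[factor]])
  ev <- as.integer(df$event)
  tab <- table(f, factor(ev, levels = c(0, 1)))
  cen <- as.vector(tab[, 1]); evn <- as.vector(tab[, 2])
  out <- data.frame(
    level = levels(f),
    censored_n = cen,
    censored_pct = if (sum(cen)) 100 * cen / sum(cen) else rep(NA_real_, length(cen)),
    event_n = evn,
    event_pct = if (sum(evn)) 100 * evn / sum(evn) else rep(NA_real_, length(evn)))
  class(out) <- c("status_crosstab", "data.frame")
  attr(out, "factor") <- factor
  out
}

#' State-level spatial effect summaries
#'
#' Posterior mean and sd of each state's spatial effect and its time ratio
#' `exp(mean s)`, optionally binned for choropleth display.
#'
#' @param samples an `icar_samples` fitted with the ICAR effect on.
#' @param graph the [adjacency_graph] (for component bookkeeping).
#' @param labels optional replacement state labels.
#' @return data.frame of class `spatial_effect_table` with columns `state`,
#'   `mean`, `sd`, `time_ratio` (and `bin`/`bin_label` after
#'   [bin_spatial_effects()]).
#' @export
spatial_effect_table <- function(samples, graph, labels = NULL) {
  stopifnot(inherits(samples, "icar_samples"))
  if (!samples$spec$include_icar)
    stop("model was fitted without the Besag ICAR effect; ",
         "state-level spatial summaries are meaningless for it")
  G <- ncol(samples$s)
  if (!is.null(labels) && length(labels) != G)
    stop("labels length mismatch")
  if (is.null(labels)) labels <- samples$state_labels
  mn <- colMeans(samples$s)
  out <- data.frame(state = labels, mean = mn,
                    sd = apply(samples$s, 2, stats::sd),
                    time_ratio = time_ratio(mn), row.names = NULL)
  class(out) <- c("spatial_effect_table", "data.frame")
  out
}

#' Default and preset time-ratio bin breaks
#'
#' `"default"`: clean symmetric five-bin breaks on the TR scale.
#' `"fig3"`: an approximate reconstruction of the irregular verbal
#' percentage bands used in the reference choropleth of debut risk
#' (approximate: exact break values were never printed).
#'
#' @param preset `"default"` or `"fig3"`.
#' @return strictly increasing numeric breaks (interior breaks of 5 bins).
#' @export
tr_breaks <- function(preset = c("default", "fig3")) {
  preset <- match.arg(preset)
  switch(preset,
         default = c(0.80, 0.95, 1.05, 1.25),
         fig3 = c(0.80, 0.95, 1.12, 1.24))
}

.bin_labels <- c("strong_deceleration", "mild_deceleration", "near_null",
                 "mild_acceleration", "strong_acceleration")

#' Bin state time ratios for choropleth display
#'
#' Assigns each state's TR to one of `length(breaks) + 1` left-closed,
#' right-open bins; a TR exactly on a break belongs to the upper bin. The
#' default five bins follow a diverging scheme from strong deceleration
#' (TR well below 1, earlier debut) to strong acceleration (TR well above
#' 1, delayed debut).
#'
#' @param table a [spatial_effect_table()] result.
#' @param breaks strictly increasing interior break points on the TR
#'   scale.
#' @return the table with `bin` (integer) and `bin_label` columns added.
#' @export
bin_spatial_effects <- function(table, breaks = tr_breaks("default")) {
  stopifnot(inherits(table, "spatial_effect_table"))
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  table$bin <- findInterval(table$time_ratio, breaks) + 1L
  labels <- if (length(breaks) == 4) .bin_labels else
    paste0("bin", seq_len(length(breaks) + 1))
  table$bin_label <- labels[table$bin]
  table
}

.norm_key <- function(x) tolower(gsub("\\s+", " ", trimws(as.character(x))))

#' Export spatial effects as a choropleth
#'
#' Joins a binned [spatial_effect_table()] onto user-supplied GeoJSON
#' polygons by a key property (case-insensitive, whitespace-normalised),
#' writes the joined GeoJSON with `time_ratio`, `bin` and `bin_label`
#' properties, and optionally renders a static choropleth image. States in
#' the table that match no polygon are an error (nothing is dropped
#' silently).
#'
#' @param table a binned `spatial_effect_table` (run
#'   [bin_spatial_effects()] first; unbinned tables are binned with
#'   default breaks).
#' @param geojson path to a GeoJSON `FeatureCollection` of polygons.
#' @param key_field name of the feature property holding the state label.
#' @param out_geojson output path for the joined GeoJSON.
#' @param out_image optional PNG path for a rendered map.
#' @return invisibly, a list with `matched`, `unmatched_features` (polygon
#'   keys with no table entry; reported, not an error) and the output
#'   paths.
#' @export
export_choropleth <- function(table, geojson, key_field, out_geojson,
                              out_image = NULL) {
  stopifnot(inherits(table, "spatial_effect_table"))
  if (is.null(table$bin)) table <- bin_spatial_effects(table)
  gj <- jsonlite::read_json(geojson, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("GeoJSON is not a FeatureCollection")
  keys <- vapply(gj$features, function(f) {
    v <- f$properties[[key_field]]
    if (is.null(v)) stop("feature without key property '", key_field, "'")
    as.character(v)
  }, "")
  idx <- match(.norm_key(table$state), .norm_key(keys))
  if (anyNA(idx))
    stop("state(s) with no matching polygon: ",
         paste(table$state[is.na(idx)], collapse = ", "))
  for (r in seq_len(nrow(table))) {
    f <- idx[r]
    gj$features[[f]]$properties$time_ratio <- table$time_ratio[r]
    gj$features[[f]]$properties$bin <- table$bin[r]
    gj$features[[f]]$properties$bin_label <- table$bin_label[r]
  }
  jsonlite::write_json(gj, out_geojson, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  if (!is.null(out_image))
    .render_choropleth(gj, idx, table, out_image)
  invisible(list(matched = length(idx),
                 unmatched_features = setdiff(seq_along(keys), idx),
                 geojson = out_geojson, image = out_image))
}

# minimal static renderer for Polygon/MultiPolygon features
.render_choropleth <- function(gj, idx, table, path) {
  pal <- c("#1a9850", "#91cf60", "#ffffbf", "#fc8d59", "#d73027")
  rings <- function(geom) {
    if (geom$type == "Polygon") list(geom$coordinates) else
      if (geom$type == "MultiPolygon") geom$coordinates else
        stop("unsupported geometry type: ", geom$type)
  }
  all_xy <- do.call(rbind, lapply(gj$features, function(f)
    do.call(rbind, lapply(rings(f$geometry), function(poly)
      do.call(rbind, lapply(poly[[1]], function(pt)
        c(pt[[1]], pt[[2]])))))))
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  graphics::plot(all_xy, type = "n", asp = 1, xlab = "", ylab = "",
                 main = "State-level time ratios", axes = FALSE)
  for (r in seq_len(nrow(table))) {
    f <- gj$features[[idx[r]]]
    col <- pal[min(table$bin[r], length(pal))]
    for (poly in rings(f$geometry)) {
      xy <- do.call(rbind, lapply(poly[[1]], function(pt) c(pt[[1]], pt[[2]])))
      graphics::polygon(xy, col = col, border = "grey30")
    }
  }
  graphics::legend("bottomleft", legend = .bin_labels, fill = pal, bty = "n")
  invisible(path)
}

#' Write a fixed-effects table to CSV
#'
#' Values are written at full precision so a round-trip through
#' [utils::read.csv()] reproduces them exactly.
#'
#' @param table a `fixed_effects_table` (or any data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixed_effects <- function(table, path) {
  df <- as.data.frame(table)
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
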