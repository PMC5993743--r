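map_meta <- function(map) {
  list(interval = map$cfg$interval, horizon = map$cfg$horizon, m = map$cfg$m,
       family_alpha = map$sel_cfg$family_alpha, alpha = map$sel_cfg$alpha,
       min_level_count = map$sel_cfg$min_level_count, gate = map$gate,
       epv = map$epv, min_node = map$min_node, n_paths = map$n_paths,
       ties = "efron", feature_names = map$feature_names,
       long_term_paths = map$long_term_paths)
}

#' Configuration hash of a map
#'
#' MD5 digest of the map's configuration echo; every serialized artifact
#' embeds it so outputs from different configurations are distinguishable.
#'
#' @param map a `survival_map`.
#' @return hex string.
#' @export
map_hash <- function(map) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(map_meta(map), tf, auto_unbox = TRUE, digits = I(17))
  unname(tools::md5sum(tf))
}

#' Serialize a survival map to JSON (and back)
#'
#' JSON is the canonical on-disk format for a built map: configuration echo
#' with hash, per-slice subclass counts, the root split, and every node with
#' its members, median, links and classification.  `read_map` reconstructs
#' an equivalent `survival_map`.
#'
#' @param map a `survival_map`.
#' @param path output file.
#' @return `read_map` returns a `survival_map`.
#' @export
write_map <- function(map, path) {
  nodes <- lapply(unname(map$nodes), function(nd)
    nd[c("p", "ts", "id", "members", "n", "median", "curve_max", "excluded",
         "parent_id", "split_feature", "upper_id", "lower_id", "upper_value",
         "child_id", "classification")])
  tr <- lapply(map$transitions, function(t)
    list(node = t$node, counts = as.vector(t$table), method = t$method,
         p_value = t$p_value, surgery_rate = t$surgery_rate,
         up_given_treatment = t$up_given_treatment))
  obj <- list(format = "survival_map", config = map_meta(map),
              config_hash = map_hash(map),
              slice_counts = map$slice_counts,
              root = map$root[c("id", "n", "split_feature", "upper_id",
                                "lower_id", "upper_value", "child_id")],
              nodes = nodes, transitions = tr)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfgj <- obj$config
  sc <- function(x, as = identity) if (is.null(x)) NA else as(x)
  nodes <- list()
  for (ndj in obj$nodes) {
    nd <- structure(list(
      p = as.integer(ndj$p), ts = as.integer(ndj$ts), id = ndj$id,
      members = as.character(unlist(ndj$members)),
      n = as.integer(ndj$n), median = sc(ndj$median, as.numeric),
      curve_max = sc(ndj$curve_max, as.numeric),
      excluded = isTRUE(ndj$excluded),
      parent_id = sc(ndj$parent_id, as.character),
      split_feature = sc(ndj$split_feature, as.character),
      upper_id = sc(ndj$upper_id, as.character),
      lower_id = sc(ndj$lower_id, as.character),
      upper_value = sc(ndj$upper_value, as.integer),
      child_id = sc(ndj$child_id, as.character),
      classification = as.character(unlist(ndj$classification)),
      trace = NULL), class = "sp_node")
    nodes[[nd$id]] <- nd
  }
  root <- list(id = "root", n = as.integer(obj$root$n),
               split_feature = sc(obj$root$split_feature, as.character),
               upper_id = sc(obj$root$upper_id, as.character),
               lower_id = sc(obj$root$lower_id, as.character),
               upper_value = sc(obj$root$upper_value, as.integer),
               child_id = sc(obj$root$child_id, as.character), trace = NULL)
  map <- structure(list(
    nodes = nodes, root = root,
    cfg = slice_config(cfgj$interval, cfgj$horizon),
    sel_cfg = selection_config(cfgj$family_alpha, cfgj$m, cfgj$min_level_count),
    gate = cfgj$gate, epv = cfgj$epv, min_node = as.integer(cfgj$min_node),
    feature_names = as.character(unlist(cfgj$feature_names)),
    n_paths = as.integer(cfgj$n_paths),
    long_term_paths = as.integer(unlist(cfgj$long_term_paths))),
    class = "survival_map")
  map$slice_counts <- slice_counts(map)
  map
}

#' DOT export of a survival map
#'
#' @param map a `survival_map`.
#' @param path output `.dot` file.
#' @param include_excluded render nodes with fewer members than the minimum
#'   (dashed) instead of dropping them.
#' @return invisibly, the path.
#' @export
write_map_dot <- function(map, path, include_excluded = FALSE) {
  lab <- function(nd) sprintf("S(p=%d, ts=%d)\\nn=%d, med=%s", nd$p, nd$ts,
                              nd$n, ifelse(is.na(nd$median), "NR",
                                           sprintf("%.1f", nd$median)))
  keep <- function(nd) include_excluded || !nd$excluded
  lines <- c("digraph survival_map {", "  rankdir=LR;",
             sprintf("  // config %s", map_hash(map)),
             sprintf("  root [label=\"S(all; ts=1)\\nn=%d\", shape=box];",
                     map$root$n))
  for (nd in map$nodes) {
    if (!keep(nd)) next
    style <- if (nd$excluded) ", style=dashed" else ""
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"%s];", nd$id, lab(nd), style))
  }
  edge <- function(from, nd_id, tag) {
    nd <- map$nodes[[nd_id]]
    if (is.null(nd) || !keep(nd)) return(character(0))
    sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];", from, nd_id, tag)
  }
  holders <- c(list(map$root), unname(map$nodes))
  for (h in holders) {
    from <- if (identical(h$id, "root")) "root" else h$id
    if (!identical(h$id, "root") && !keep(h)) next
    if (!is.na(h$split_feature)) {
      lines <- c(lines,
                 edge(from, h$upper_id, sprintf("%s=%d", h$split_feature,
                                                h$upper_value)),
                 edge(from, h$lower_id, sprintf("%s=%d", h$split_feature,
                                                1L - h$upper_value)))
    } else if (!is.na(h$child_id)) {
      lines <- c(lines, edge(from, h$child_id, ""))
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Plot a survival map
#'
#' Two-dimensional rendering of the map: time slices on the x-axis, node
#' median OS on the y-axis, one polyline per path.  Nodes whose median is
#' not reached and excluded (<`min_node`) nodes are omitted.
#'
#' @param x a `survival_map`.
#' @param lwd,pch usual graphics parameters.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data frame of plotted coordinates.
#' @export
plot.survival_map <- function(x, lwd = 2, pch = 19, ...) {
  df <- map_nodes_df(x)
  df <- df[!df$excluded & !is.na(df$median_os), , drop = FALSE]
  if (nrow(df) == 0L) stop("nothing to plot: no rendered node has a median")
  cols <- grDevices::hcl.colors(max(df$p), "Dark 3")
  graphics::plot(range(df$ts), range(df$median_os), type = "n",
                 xlab = "time slice", ylab = "median OS (months)", ...)
  for (p in sort(unique(df$p))) {
    sub <- df[df$p == p, , drop = FALSE]
    sub <- sub[order(sub$ts), , drop = FALSE]
    graphics::lines(sub$ts, sub$median_os, col = cols[p], lwd = lwd)
    graphics::points(sub$ts, sub$median_os, col = cols[p], pch = pch)
  }
  graphics::legend("topleft", legend = paste("path", sort(unique(df$p))),
                   col = cols[sort(unique(df$p))], lwd = lwd, cex = 0.7,
                   bty = "n")
  invisible(df)
}
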