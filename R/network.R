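# Aggregation of dyadic results into an interaction network.

#' Build an interaction network from per-dyad segments
#'
#' One edge per dyad with at least one concurrent interaction segment,
#' weighted by segment count and total duration; monthly normalisation uses
#' each dyad's shared tracking span (calendar months in which both
#' individuals have at least one fix). Individuals without any edge are
#' listed separately as isolates.
#'
#' @param dyad_segments Named list: `"A|B"` -> concurrent
#'   `"interaction_segments"` table for that dyad.
#' @param tracks Optional `"tracks"` object used for shared-month counts and
#'   the isolate list.
#' @return Object of class `"interaction_network"`: list with `nodes`
#'   (id, degree, n_segments, total_duration_h), `edges` (id_a, id_b,
#'   n_segments, total_duration_h, months_shared, duration_per_month_h) and
#'   `isolates`.
#' @export
build_network <- function(dyad_segments, tracks = NULL) {
  edges <- list()
  for (key in names(dyad_segments)) {
    ids <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (length(ids) != 2) stop(sprintf("dyad key not of the form 'A|B': %s", key))
    seg <- dyad_segments[[key]]
    if (is.null(seg) || !nrow(seg)) next
    months_shared <- NA_integer_
    if (!is.null(tracks)) {
      tz <- tracks$tz
      ma <- unique(format(track_of(tracks, ids[1])$t, "%Y-%m", tz = tz))
      mb <- unique(format(track_of(tracks, ids[2])$t, "%Y-%m", tz = tz))
      months_shared <- length(intersect(ma, mb))
    }
    tot <- sum(seg$duration_h)
    edges[[length(edges) + 1]] <- data.frame(
      id_a = min(ids), id_b = max(ids),
      n_segments = nrow(seg), total_duration_h = tot,
      months_shared = months_shared,
      duration_per_month_h = if (!is.na(months_shared) && months_shared > 0)
        tot / months_shared else NA_real_,
      stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(id_a = character(0), id_b = character(0),
                           n_segments = integer(0), total_duration_h = numeric(0),
                           months_shared = integer(0),
                           duration_per_month_h = numeric(0))
  edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$id_a, edges$id_b)))
  nodes <- do.call(rbind, lapply(ids, function(i) {
    inc <- edges$id_a == i | edges$id_b == i
    data.frame(id = i, degree = sum(inc),
               n_segments = sum(edges$n_segments[inc]),
               total_duration_h = sum(edges$total_duration_h[inc]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes))
    nodes <- data.frame(id = character(0), degree = integer(0),
                        n_segments = integer(0), total_duration_h = numeric(0))
  isolates <- if (!is.null(tracks)) setdiff(track_ids(tracks), ids) else character(0)
  structure(list(nodes = nodes, edges = edges, isolates = isolates),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d node(s), %d edge(s), %d isolate(s)\n",
              nrow(x$nodes), nrow(x$edges), length(x$isolates)))
  invisible(x)
}

#' Export a network to CSV and/or GEXF
#'
#' Writes `nodes.csv` and `edges.csv`, and a GEXF 1.2 XML file usable by
#' external network-visualisation tools.
#'
#' @param net An `"interaction_network"`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "gexf")`.
#' @return Character vector of written paths, invisibly.
#' @export
export_network <- function(net, dir, formats = c("csv", "gexf")) {
  bad <- setdiff(formats, c("csv", "gexf"))
  if (length(bad))
    stop(sprintf("unsupported format(s): %s (supported: csv, gexf)",
                 paste(bad, collapse = ", ")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("csv" %in% formats) {
    pn <- file.path(dir, "nodes.csv"); pe <- file.path(dir, "edges.csv")
    utils::write.csv(net$nodes, pn, row.names = FALSE)
    utils::write.csv(net$edges, pe, row.names = FALSE)
    paths <- c(paths, pn, pe)
  }
  if ("gexf" %in% formats) {
    pg <- file.path(dir, "network.gexf")
    esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", s)))
    nodes_xml <- paste(sprintf('      <node id="%s" label="%s" />',
                               esc(net$nodes$id), esc(net$nodes$id)),
                       collapse = "\n")
    e <- net$edges
    edges_xml <- paste(sprintf(
      '      <edge id="%d" source="%s" target="%s" weight="%.9f"><attvalues><attvalue for="0" value="%d" /><attvalue for="1" value="%.9f" /></attvalues></edge>',
      seq_len(nrow(e)) - 1L, esc(e$id_a), esc(e$id_b), e$total_duration_h,
      e$n_segments, e$total_duration_h), collapse = "\n")
    xml <- paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">\n',
      '  <graph defaultedgetype="undirected">\n',
      '    <attributes class="edge">\n',
      '      <attribute id="0" title="n_segments" type="integer" />\n',
      '      <attribute id="1" title="total_duration_h" type="double" />\n',
      '    </attributes>\n',
      '    <nodes>\n', nodes_xml, '\n    </nodes>\n',
      '    <edges>\n', edges_xml, '\n    </edges>\n',
      '  </graph>\n</gexf>\n')
    writeLines(xml, pg)
    paths <- c(paths, pg)
  }
  invisible(paths)
}

#' Re-import a network from its CSV export
#' @param dir Directory holding `nodes.csv` and `edges.csv`.
#' @return An `"interaction_network"` (without isolates).
#' @export
import_network_csv <- function(dir) {
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"), stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
  edges <- utils::read.csv(file.path(dir, "edges.csv"), stringsAsFactors = FALSE,
                           colClasses = c(id_a = "character", id_b = "character"))
  structure(list(nodes = nodes, edges = edges, isolates = character(0)),
            class = "interaction_network")
}
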