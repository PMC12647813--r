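# Semantic narrative network: per-video weighted graph whose nodes are events
# and whose edge weights are cosine similarities between the events' embedded
# descriptions. Semantic centrality of an event = its weighted degree (sum of
# off-diagonal similarities), normalized by the sum of all degrees in the
# video, then z-scored within the video.

#' Pairwise similarity matrix for one video's events
#'
#' @param embedding a `narrec_embedding` of the video's event descriptions, in
#'   event order.
#' @param video_id identifier attached to the result.
#' @return `narrec_similarity`: list with `video_id`, `n`, and the symmetric
#'   `n x n` matrix `S` with unit diagonal.
#' @export
build_similarity <- function(embedding, video_id = "video") {
  stopifnot(inherits(embedding, "narrec_embedding"))
  V <- embedding$vectors
  n <- nrow(V)
  if (n < 2L) stop("need at least 2 events to build a network", call. = FALSE)
  zero <- rowSums(V^2) == 0
  if (any(zero)) {
    stop(
      "all-zero embedding for event(s) ", paste(which(zero), collapse = ", "),
      ": no tokens to embed", call. = FALSE
    )
  }
  # rows are unit norm, so the Gram matrix is the cosine matrix
  S <- tcrossprod(V / sqrt(rowSums(V^2)))
  S <- (S + t(S)) / 2
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  structure(list(video_id = video_id, n = n, S = S), class = "narrec_similarity")
}

#' Semantic centrality of events within a video
#'
#' For each event i: `raw_degree[i] = sum_{j != i} S[i, j]` (self-similarity is
#' excluded; edges connect distinct events), `norm_degree = raw_degree /
#' sum(raw_degree)`, and `z` = the z-score of `norm_degree` within the video.
#' The z-score uses the population (divide-by-n) standard deviation by
#' default, switchable via `sd_type = "sample"`. The `z` column is the
#' "normalized semantic centrality" predictor used by the mixed models.
#'
#' @param sim a `narrec_similarity`.
#' @param sd_type `"population"` (default) or `"sample"` standard deviation
#'   for the within-video z-score.
#' @return `narrec_centrality`: data.frame with columns `video_id`,
#'   `event_index`, `raw_degree`, `norm_degree`, `z`.
#' @export
semantic_centrality <- function(sim, sd_type = c("population", "sample")) {
  stopifnot(inherits(sim, "narrec_similarity"))
  sd_type <- match.arg(sd_type)
  S <- sim$S
  n <- sim$n
  if (n < 3L) stop("semantic centrality needs at least 3 events", call. = FALSE)
  raw <- rowSums(S) - diag(S)
  total <- sum(raw)
  if (total == 0) {
    stop("degenerate network: degrees sum to zero for video ", sim$video_id,
      call. = FALSE
    )
  }
  norm <- raw / total
  mu <- mean(norm)
  s <- sqrt(mean((norm - mu)^2))
  if (sd_type == "sample") s <- stats::sd(norm)
  if (s == 0) {
    warning(
      "all events equally central in video ", sim$video_id, "; z set to 0",
      call. = FALSE
    )
    z <- rep(0, n)
  } else {
    z <- (norm - mu) / s
  }
  structure(
    data.frame(
      video_id = sim$video_id, event_index = seq_len(n),
      raw_degree = raw, norm_degree = norm, z = z
    ),
    class = c("narrec_centrality", "data.frame")
  )
}

#' Export a semantic network as edge and node tables
#'
#' Writes `<stem>_edges.csv` (`i, j, weight` with `i < j`) and
#' `<stem>_nodes.csv` (the centrality table), and optionally
#' `<stem>.graphml` for network viewers (requires the igraph package).
#'
#' @param sim a `narrec_similarity`.
#' @param scores matching `narrec_centrality`.
#' @param stem output path stem (directory must exist).
#' @param graphml also write GraphML.
#' @return invisibly, the paths written.
#' @export
export_network <- function(sim, scores, stem, graphml = FALSE) {
  stopifnot(inherits(sim, "narrec_similarity"), inherits(scores, "narrec_centrality"))
  idx <- which(upper.tri(sim$S), arr.ind = TRUE)
  edges <- data.frame(
    i = idx[, 1], j = idx[, 2],
    weight = sim$S[idx]
  )
  edges <- edges[order(edges$i, edges$j), ]
  edge_path <- paste0(stem, "_edges.csv")
  node_path <- paste0(stem, "_nodes.csv")
  utils::write.csv(edges, edge_path, row.names = FALSE)
  utils::write.csv(as.data.frame(scores), node_path, row.names = FALSE)
  paths <- c(edge_path, node_path)
  if (graphml) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      stop("GraphML export requires the igraph package", call. = FALSE)
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::V(g)$z <- scores$z[match(as.integer(igraph::V(g)$name), scores$event_index)]
    gp <- paste0(stem, ".graphml")
    igraph::write_graph(g, gp, format = "graphml")
    paths <- c(paths, gp)
  }
  invisible(paths)
}

#' Rebuild a similarity matrix from an exported edge table
#'
#' Inverse of the edge-list half of [export_network()] (diagonal restored
#' to 1).
#'
#' @param edge_path path to an `_edges.csv` file.
#' @param video_id identifier for the rebuilt object.
#' @export
import_similarity <- function(edge_path, video_id = "video") {
  edges <- utils::read.csv(edge_path)
  n <- max(edges$i, edges$j)
  S <- diag(n)
  S[cbind(edges$i, edges$j)] <- edges$weight
  S[cbind(edges$j, edges$i)] <- edges$weight
  structure(list(video_id = video_id, n = n, S = S), class = "narrec_similarity")
}

#' Centrality for every video in an annotation set
#'
#' Convenience pipeline: embed each video's event descriptions, build the
#' similarity network, and compute centrality, returning one stacked table.
#'
#' @param videos list of `narrec_video` annotations.
#' @param backend embedding backend (default [hash_embedder()]).
#' @param include_sub_events append sub-event descriptions to the event
#'   description before embedding (default FALSE: the event-level description
#'   alone is embedded).
#' @return data.frame of per-event centrality rows for all videos.
#' @export
centrality_table <- function(videos, backend = hash_embedder(),
                             include_sub_events = FALSE) {
  out <- lapply(videos, function(v) {
    texts <- vapply(v$events, function(e) {
      if (include_sub_events && length(e$sub_event_descriptions)) {
        paste(c(e$description, e$sub_event_descriptions), collapse = " ")
      } else {
        e$description
      }
    }, character(1))
    sim <- build_similarity(embed_texts(texts, backend), video_id = v$video_id)
    as.data.frame(semantic_centrality(sim))
  })
  do.call(rbind, out)
}
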