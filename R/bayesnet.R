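#' Network structure constructor
#'
#' A directed acyclic graph over named nodes, stored as per-node parent
#' lists.
#'
#' @param nodes character vector of node names (unique).
#' @param parents named list (one entry per node) of parent name vectors;
#'   missing entries mean no parents.
#' @return object of class `network_structure`.
#' @export
network_structure <- function(nodes, parents = NULL) {
  stopifnot(!anyDuplicated(nodes))
  ps <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) ps[[v]] <- character(0)
  if (!is.null(parents)) {
    for (v in names(parents)) {
      stopifnot(v %in% nodes, all(parents[[v]] %in% nodes))
      ps[[v]] <- parents[[v]]
    }
  }
  s <- structure(list(nodes = nodes, parents = ps),
                 class = "network_structure")
  if (.is_cyclic(s)) stop("structure is cyclic")
  s
}

#' Arcs of a network structure
#' @param structure a `network_structure`.
#' @return 2-column character matrix (from, to); 0 rows for an empty graph.
#' @export
structure_arcs <- function(structure) {
  out <- do.call(rbind, lapply(structure$nodes, function(v) {
    if (length(structure$parents[[v]]))
      cbind(from = structure$parents[[v]], to = v)
  }))
  if (is.null(out)) out <- matrix(character(0), 0, 2,
                                  dimnames = list(NULL, c("from", "to")))
  out
}

.is_cyclic <- function(structure) {
  nodes <- structure$nodes
  indeg_parents <- structure$parents
  remaining <- nodes
  repeat {
    leaf <- remaining[vapply(remaining, function(v)
      !length(intersect(indeg_parents[[v]], remaining)), logical(1))]
    if (!length(leaf)) return(length(remaining) > 0)
    remaining <- setdiff(remaining, leaf)
    if (!length(remaining)) return(FALSE)
  }
}

# TRUE if a directed path v -> ... -> u exists (adding u -> v would cycle)
.has_path <- function(structure, v, u) {
  children <- stats::setNames(vector("list", length(structure$nodes)),
                              structure$nodes)
  for (w in structure$nodes)
    for (p in structure$parents[[w]]) children[[p]] <- c(children[[p]], w)
  frontier <- v; seen <- character(0)
  while (length(frontier)) {
    x <- frontier[1]; frontier <- frontier[-1]
    if (x == u) return(TRUE)
    if (x %in% seen) next
    seen <- c(seen, x)
    frontier <- c(frontier, children[[x]])
  }
  FALSE
}

#' Blacklist of forbidden directed arcs
#'
#' Helper building the endpoint constraint used for trait networks: all
#' arcs leading away from the trait nodes toward the morphological features
#' are forbidden, so traits can only be arc heads.
#'
#' @param nodes all node names.
#' @param traits trait node names (arc tails to forbid).
#' @return 2-column character matrix (from, to).
#' @export
trait_blacklist <- function(nodes, traits) {
  stopifnot(all(traits %in% nodes))
  out <- do.call(rbind, lapply(traits, function(tr)
    cbind(from = tr, to = setdiff(nodes, tr))))
  out
}

.blacklisted <- function(blacklist, from, to) {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(FALSE)
  any(blacklist[, 1] == from & blacklist[, 2] == to)
}

# Gaussian node score: log-likelihood of node | parents minus BIC penalty.
# parameters = |parents| + 2 (intercept and residual sd); higher is better.
.node_score <- function(data, node, parents, cache = NULL) {
  key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  y <- data[, node]
  n <- length(y)
  if (length(parents)) {
    Xp <- cbind(1, data[, parents, drop = FALSE])
    qx <- qr(Xp)
    if (qx$rank < ncol(Xp)) {
      val <- -Inf
      if (!is.null(cache)) cache[[key]] <- val
      return(val)
    }
    res <- stats::lm.fit(Xp, y)$residuals
  } else {
    res <- y - mean(y)
  }
  s2 <- sum(res^2) / n
  if (s2 <= 0) s2 <- 1e-300
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  val <- ll - (length(parents) + 2) / 2 * log(n)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' BIC score of a Gaussian network structure
#'
#' Sum over nodes of the Gaussian log-likelihood of the node given its
#' parents minus (parameters / 2) * log(n), with parameters = number of
#' parents + 2. This is the -2-rescaled BIC convention in which higher is
#' better, and the score is decomposable over nodes. A singular parent
#' design scores -Inf.
#'
#' @param structure a `network_structure`.
#' @param data numeric matrix whose columns cover all nodes.
#' @return scalar score (higher is better).
#' @export
bic_score <- function(structure, data) {
  data <- as.matrix(data)
  stopifnot(all(structure$nodes %in% colnames(data)))
  sum(vapply(structure$nodes, function(v)
    .node_score(data, v, structure$parents[[v]]), numeric(1)))
}

# enumerate admissible moves; returns list of lists(type, from, to)
.candidate_moves <- function(structure, blacklist) {
  nodes <- structure$nodes
  arcs <- structure_arcs(structure)
  has_arc <- function(u, v) any(arcs[, 1] == u & arcs[, 2] == v)
  moves <- list()
  for (u in nodes) for (v in nodes) {
    if (u == v) next
    if (has_arc(u, v)) {
      moves[[length(moves) + 1L]] <- list(type = "delete", from = u, to = v)
      if (!.blacklisted(blacklist, v, u))
        moves[[length(moves) + 1L]] <- list(type = "reverse", from = u, to = v)
    } else if (!.blacklisted(blacklist, u, v) && !has_arc(v, u)) {
      moves[[length(moves) + 1L]] <- list(type = "add", from = u, to = v)
    }
  }
  moves
}

.apply_move <- function(structure, mv) {
  p <- structure$parents
  if (mv$type == "add") {
    p[[mv$to]] <- sort(c(p[[mv$to]], mv$from))
  } else if (mv$type == "delete") {
    p[[mv$to]] <- setdiff(p[[mv$to]], mv$from)
  } else {
    p[[mv$to]] <- setdiff(p[[mv$to]], mv$from)
    p[[mv$from]] <- sort(c(p[[mv$from]], mv$to))
  }
  structure$parents <- p
  structure
}

.move_ok <- function(structure, mv) {
  if (mv$type == "add") return(!.has_path(structure, mv$to, mv$from))
  if (mv$type == "reverse") {
    tmp <- structure
    tmp$parents[[mv$to]] <- setdiff(tmp$parents[[mv$to]], mv$from)
    return(!.has_path(tmp, mv$from, mv$to))
  }
  TRUE
}

# score change of a move, using the per-node cache
.move_delta <- function(data, structure, mv, cache) {
  after <- .apply_move(structure, mv)
  touched <- if (mv$type == "reverse") c(mv$from, mv$to) else mv$to
  sum(vapply(touched, function(v)
    .node_score(data, v, after$parents[[v]], cache) -
      .node_score(data, v, structure$parents[[v]], cache), numeric(1)))
}

.move_key <- function(mv) paste(mv$type, mv$from, mv$to)

.climb_once <- function(data, start, blacklist, cache, max_iter = 500L) {
  structure <- start
  for (it in seq_len(max_iter)) {
    moves <- .candidate_moves(structure, blacklist)
    deltas <- rep(-Inf, length(moves))
    for (i in seq_along(moves)) {
      if (!.move_ok(structure, moves[[i]])) next
      deltas[i] <- .move_delta(data, structure, moves[[i]], cache)
    }
    if (!length(moves) || max(deltas) <= 1e-9) break
    # score-equivalent moves (e.g. the two orientations of a fresh arc on
    # two nodes) tie exactly; break ties at random so bootstrap direction
    # confidence is uninformative when the data carry no orienting signal.
    # Reproducible under set.seed().
    tied <- which(deltas > max(deltas) - 1e-9)
    best_mv <- moves[[tied[sample.int(length(tied), 1L)]]]
    structure <- .apply_move(structure, best_mv)
  }
  structure
}

#' Hill-climbing structure search
#'
#' Greedy search from the empty graph over single-arc additions, deletions
#' and reversals, each respecting acyclicity and the blacklist, until no
#' move improves the BIC score. With `restarts > 0`, additional climbs are
#' started from randomly perturbed copies of the incumbent and the best-
#' scoring result is returned.
#'
#' @param data numeric matrix (columns = nodes).
#' @param blacklist 2-column (from, to) matrix of forbidden arcs, or NULL.
#' @param restarts number of random restarts.
#' @return a `network_structure`.
#' @export
hill_climb <- function(data, blacklist = NULL, restarts = 0L) {
  data <- as.matrix(data)
  cache <- new.env(parent = emptyenv())
  empty <- network_structure(colnames(data))
  best <- .climb_once(data, empty, blacklist, cache)
  best_score <- bic_score(best, data)
  if (restarts > 0L) {
    for (r in seq_len(restarts)) {
      pert <- best
      arcs <- structure_arcs(pert)
      # randomly delete up to 2 arcs and attempt 2 random additions
      if (nrow(arcs)) {
        k <- sample.int(min(2L, nrow(arcs)), 1L)
        for (i in sample.int(nrow(arcs), k)) {
          pert$parents[[arcs[i, 2]]] <-
            setdiff(pert$parents[[arcs[i, 2]]], arcs[i, 1])
        }
      }
      for (j in 1:2) {
        uv <- sample(pert$nodes, 2)
        mv <- list(type = "add", from = uv[1], to = uv[2])
        arcs_now <- structure_arcs(pert)
        if (!any(arcs_now[, 1] == uv[1] & arcs_now[, 2] == uv[2]) &&
            !any(arcs_now[, 1] == uv[2] & arcs_now[, 2] == uv[1]) &&
            !.blacklisted(blacklist, uv[1], uv[2]) &&
            !.has_path(pert, uv[2], uv[1]))
          pert <- .apply_move(pert, mv)
      }
      cand <- .climb_once(data, pert, blacklist, cache)
      sc <- bic_score(cand, data)
      if (sc > best_score + 1e-9) { best <- cand; best_score <- sc }
    }
  }
  best
}

#' Tabu structure search
#'
#' Hill climbing that, once no improving move exists, keeps taking the best
#' admissible non-improving move while forbidding recently visited
#' structures (signature tabu list), for up to `max_stagnation` steps
#' without improvement. The best structure encountered is returned; with
#' `tabu_length = 0` and `max_stagnation = 0` this reduces exactly to
#' [hill_climb()].
#'
#' @param data numeric matrix (columns = nodes).
#' @param blacklist forbidden (from, to) arcs, or NULL.
#' @param tabu_length number of recent structure signatures kept forbidden.
#' @param max_stagnation non-improving steps allowed before stopping.
#' @return a `network_structure`.
#' @export
tabu_search <- function(data, blacklist = NULL, tabu_length = 10L,
                        max_stagnation = 10L) {
  data <- as.matrix(data)
  cache <- new.env(parent = emptyenv())
  sig <- function(s) paste(apply(structure_arcs(s), 1, paste, collapse = ">"),
                           collapse = ";")
  current <- network_structure(colnames(data))
  best <- current
  best_score <- bic_score(best, data)
  cur_score <- best_score
  tabu <- character(0)
  stagnation <- 0L
  repeat {
    moves <- .candidate_moves(current, blacklist)
    deltas <- rep(-Inf, length(moves))
    for (i in seq_along(moves)) {
      mv <- moves[[i]]
      if (!.move_ok(current, mv)) next
      if (sig(.apply_move(current, mv)) %in% tabu) next
      deltas[i] <- .move_delta(data, current, mv, cache)
    }
    if (!length(moves) || all(!is.finite(deltas))) break
    tied <- which(deltas > max(deltas) - 1e-9)
    best_mv <- moves[[tied[sample.int(length(tied), 1L)]]]
    best_delta <- max(deltas)
    tabu <- c(sig(current), tabu)
    if (length(tabu) > max(tabu_length, 0L))
      tabu <- tabu[seq_len(max(tabu_length, 0L))]
    current <- .apply_move(current, best_mv)
    cur_score <- cur_score + best_delta
    if (cur_score > best_score + 1e-9) {
      best <- current; best_score <- cur_score; stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
      if (stagnation > max_stagnation) break
    }
  }
  best
}

#' Bootstrap model averaging of network structures
#'
#' Learns a structure on each of `replicates` row resamples and summarises
#' arc support: the strength of an (undirected) arc is the fraction of
#' replicates whose learned structure contains it in either direction, and
#' the direction confidence of u -> v is the fraction of those containing
#' that orientation. Failed replicates are retried with a fresh resample
#' and counted.
#'
#' @param data numeric matrix (columns = nodes).
#' @param algorithm "hc" or "tabu".
#' @param replicates number of bootstrap replicates (the reference protocol
#'   uses 5000; tests use fewer).
#' @param blacklist forbidden (from, to) arcs, or NULL.
#' @param ... passed to the search algorithm.
#' @return list of class `arc_confidence`: `arcs` (data.frame from, to,
#'   strength, direction_confidence, both orientations per supported pair),
#'   `replicates`, `failures`.
#' @export
bootstrap_average <- function(data, algorithm = c("hc", "tabu"),
                              replicates = 5000L, blacklist = NULL, ...) {
  algorithm <- match.arg(algorithm)
  data <- as.matrix(data)
  n <- nrow(data)
  nodes <- colnames(data)
  learner <- if (algorithm == "hc") hill_climb else tabu_search
  dir_count <- matrix(0L, length(nodes), length(nodes),
                      dimnames = list(nodes, nodes))
  failures <- 0L
  done <- 0L
  while (done < replicates) {
    rows <- sample.int(n, n, replace = TRUE)
    st <- tryCatch(learner(data[rows, , drop = FALSE], blacklist, ...),
                   error = function(e) NULL)
    if (is.null(st)) { failures <- failures + 1L
      if (failures > 10L * replicates) stop("too many replicate failures")
      next }
    arcs <- structure_arcs(st)
    if (nrow(arcs))
      for (i in seq_len(nrow(arcs)))
        dir_count[arcs[i, 1], arcs[i, 2]] <-
          dir_count[arcs[i, 1], arcs[i, 2]] + 1L
    done <- done + 1L
  }
  und <- dir_count + t(dir_count)
  out <- NULL
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i == j || und[i, j] == 0L) next
    out <- rbind(out, data.frame(
      from = nodes[i], to = nodes[j],
      strength = und[i, j] / replicates,
      direction_confidence = dir_count[i, j] / und[i, j]))
  }
  if (is.null(out))
    out <- data.frame(from = character(0), to = character(0),
                      strength = numeric(0), direction_confidence = numeric(0))
  structure(list(arcs = out, replicates = replicates, failures = failures),
            class = "arc_confidence")
}

#' Consensus network from bootstrap arc confidences
#'
#' Keeps arcs with strength at or above the threshold, orients each by its
#' majority direction confidence, and resolves residual cycles by inserting
#' arcs in decreasing strength order and skipping any arc that would close
#' a cycle (equivalently: the weakest arc of every cycle is dropped).
#'
#' @param confidence an `arc_confidence` from [bootstrap_average()].
#' @param threshold minimum strength (default 0.5, the conventional
#'   model-averaging cut).
#' @return a `network_structure`.
#' @export
averaged_network <- function(confidence, threshold = 0.5) {
  arcs <- confidence$arcs
  nodes <- sort(unique(c(arcs$from, arcs$to)))
  if (!nrow(arcs)) return(network_structure(nodes))
  # one row per unordered pair, majority orientation
  key <- apply(cbind(pmin(arcs$from, arcs$to), pmax(arcs$from, arcs$to)),
               1, paste, collapse = "~")
  pick <- arcs[arcs$direction_confidence >= 0.5, ]
  pick_key <- key[arcs$direction_confidence >= 0.5]
  keep <- !duplicated(pick_key) & pick$strength >= threshold
  pick <- pick[keep, , drop = FALSE]
  st <- network_structure(nodes)
  if (nrow(pick)) {
    ord <- order(-pick$strength, pick$from, pick$to)
    for (i in ord) {
      if (!.has_path(st, pick$to[i], pick$from[i]))
        st$parents[[pick$to[i]]] <- sort(c(st$parents[[pick$to[i]]],
                                           pick$from[i]))
    }
  }
  st
}
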