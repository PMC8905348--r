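#' @include enumerate.R
NULL

#' Per-reaction occurrence statistics over enumerated solutions
#'
#' One row per (original reaction, direction) pair that is active in at least
#' one solution: how many solutions use it, the percentage over all
#' solutions, and the mean moles passed when active. Forward and reverse
#' copies of a split reversible reaction are counted separately; they never
#' co-occur within one solution.
#'
#' @param ss a \linkS4class{SolutionSet}.
#' @param net the \linkS4class{SplitNetwork} the solutions were computed on.
#' @return data.frame with columns \code{reaction}, \code{direction},
#'   \code{occurrence_count}, \code{occurrence_pct}, \code{mean_phi}.
#' @export
occurrenceTable <- function(ss, net) {
  stopifnot(is(ss, "SolutionSet"), is(net, "SplitNetwork"))
  nsol <- length(ss@solutions)
  if (nsol == 0L) stop("empty solution set")
  org <- net@origin
  ids <- reactionIds(net)
  count <- stats::setNames(integer(length(ids)), ids)
  phisum <- stats::setNames(numeric(length(ids)), ids)
  for (s in ss@solutions) {
    act <- s@support
    count[act] <- count[act] + 1L
    phisum[act] <- phisum[act] + s@phi[act]
  }
  keep <- count > 0L
  tbl <- data.frame(
    reaction = org$origin[keep],
    direction = org$direction[keep],
    occurrence_count = unname(count[keep]),
    occurrence_pct = unname(100 * count[keep] / nsol),
    mean_phi = unname(phisum[keep] / count[keep]),
    stringsAsFactors = FALSE)
  rownames(tbl) <- NULL
  tbl[order(-tbl$occurrence_pct, tbl$reaction, tbl$direction), , drop = FALSE]
}

#' Predicted metabolite variations per solution
#'
#' For every solution and metabolite, the net production (S phi)_i over the
#' transition, flagged by measurement status and direction of change.
#'
#' @param ss a \linkS4class{SolutionSet}.
#' @param net the \linkS4class{SplitNetwork}.
#' @param bounds optional \linkS4class{BoundVectors}; when given, the
#'   \code{measured} flag is filled in.
#' @return data.frame with columns \code{solution}, \code{metabolite},
#'   \code{variation}, \code{measured}, \code{change}
#'   (accumulation/depletion/none).
#' @export
predictedVariations <- function(ss, net, bounds = NULL) {
  stopifnot(is(ss, "SolutionSet"), is(net, "SplitNetwork"))
  mids <- metaboliteIds(net)
  measured <- if (is.null(bounds)) rep(NA, length(mids)) else bounds@measured
  out <- vector("list", length(ss@solutions))
  for (k in seq_along(ss@solutions)) {
    v <- ss@solutions[[k]]@predictedVariation
    out[[k]] <- data.frame(
      solution = k, metabolite = mids, variation = unname(v),
      measured = measured,
      change = ifelse(abs(v) <= 1e-9, "none",
                      ifelse(v > 0, "accumulation", "depletion")),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Export occurrence percentages as pathway-map reaction data
#'
#' Writes the JSON reaction-data mapping consumed by pathway-map viewers:
#' original reaction id to signed occurrence percentage, positive for the
#' forward direction and negative for the reverse. When both directions of
#' one reversible reaction occur (in different solutions), both are exported
#' under direction-suffixed ids with a warning.
#'
#' @param tbl an occurrence table from \code{\link{occurrenceTable}}.
#' @param path output JSON file path.
#' @return the named numeric mapping, invisibly.
#' @export
exportEscher <- function(tbl, path) {
  mapping <- list()
  both <- intersect(tbl$reaction[tbl$direction == "forward"],
                    tbl$reaction[tbl$direction == "reverse"])
  if (length(both))
    warning("both directions occur for: ", paste(both, collapse = ", "),
            "; exporting direction-suffixed entries")
  for (i in seq_len(nrow(tbl))) {
    rid <- tbl$reaction[i]
    val <- tbl$occurrence_pct[i]
    if (tbl$direction[i] == "reverse") val <- -val
    key <- if (rid %in% both)
      paste0(rid, if (tbl$direction[i] == "reverse") "_rev" else "_fwd")
    else rid
    mapping[[key]] <- val
  }
  jsonlite::write_json(mapping, path, auto_unbox = TRUE, digits = NA)
  invisible(unlist(mapping))
}

#' Distance between two occurrence tables
#'
#' Aggregates |occurrence_pct_a - occurrence_pct_b| over the union of
#' (reaction, direction) rows, with rows absent from one table counted as 0
#' percent. Symmetric; zero iff the tables coincide on the union.
#'
#' @param a,b occurrence tables from \code{\link{occurrenceTable}}.
#' @param aggregate \code{"mean"} (default) or \code{"max"}.
#' @return non-negative scalar distance, in percentage points.
#' @export
occurrenceDistance <- function(a, b, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  key <- function(x) paste(x$reaction, x$direction, sep = "\r")
  keys <- union(key(a), key(b))
  pa <- stats::setNames(rep(0, length(keys)), keys)
  pb <- pa
  pa[key(a)] <- a$occurrence_pct
  pb[key(b)] <- b$occurrence_pct
  d <- abs(pa - pb)
  if (aggregate == "mean") mean(d) else if (length(d)) max(d) else 0
}

#' Robustness of the predictions to excluded measurements
#'
#' Re-runs enumeration with subsets of the measured metabolites removed and
#' reports, for each exclusion set, the distance between the reduced and the
#' full occurrence tables. Small distances mean the prediction does not hinge
#' on the excluded measurements.
#'
#' @param net a \linkS4class{SplitNetwork}.
#' @param ms the full \linkS4class{MeasurementSet}.
#' @param exclusions list of character vectors of measured metabolite ids to
#'   drop (the empty vector gives the self-comparison, distance 0).
#' @param lambda,theta,n_max,... passed to \code{\link{buildProblem}} and
#'   \code{\link{enumerateSolutions}}.
#' @param aggregate distance aggregation, \code{"mean"} or \code{"max"}.
#' @return data.frame with columns \code{excluded}, \code{distance},
#'   \code{n_solutions}.
#' @export
robustnessAnalysis <- function(net, ms, exclusions, lambda, n_max,
                               theta = 1e-4, aggregate = c("mean", "max"),
                               ...) {
  aggregate <- match.arg(aggregate)
  measured <- ms@intervals$metabolite_id
  for (ex in exclusions) {
    if (!all(ex %in% measured))
      stop("exclusion names unmeasured metabolite(s): ",
           paste(setdiff(ex, measured), collapse = ", "))
    if (length(setdiff(measured, ex)) == 0L)
      stop("an exclusion set removes every measured metabolite")
  }
  run <- function(m) {
    p <- buildProblem(net, buildBoundVectors(net, m), lambda = lambda,
                      theta = theta, ...)
    enumerateSolutions(p, n_max = n_max)
  }
  full <- run(ms)
  fullTbl <- occurrenceTable(full, net)
  out <- data.frame(excluded = character(), distance = numeric(),
                    n_solutions = integer(), stringsAsFactors = FALSE)
  for (ex in exclusions) {
    if (length(ex) == 0L) {
      out[nrow(out) + 1L, ] <- list("", 0, length(full@solutions))
      next
    }
    red <- ms
    red@intervals <- red@intervals[!red@intervals$metabolite_id %in% ex, ,
                                   drop = FALSE]
    rss <- tryCatch(run(red), error = function(e) NULL)
    redTbl <- if (is.null(rss))
      # reduced problem infeasible: nothing is predicted active
      data.frame(reaction = character(), direction = character(),
                 occurrence_count = integer(), occurrence_pct = numeric(),
                 mean_phi = numeric(), stringsAsFactors = FALSE)
    else occurrenceTable(rss, net)
    d <- occurrenceDistance(fullTbl, redTbl, aggregate = aggregate)
    out[nrow(out) + 1L, ] <- list(paste(ex, collapse = ","), d,
                                  if (is.null(rss)) 0L else length(rss@solutions))
  }
  out
}

#' Seeded random exclusion sets for robustness testing
#'
#' @param ms a \linkS4class{MeasurementSet}.
#' @param k number of sets.
#' @param size metabolites removed per set.
#' @param seed RNG seed.
#' @return list of character vectors.
#' @export
randomExclusionSets <- function(ms, k, size, seed) {
  measured <- ms@intervals$metabolite_id
  if (size >= length(measured))
    stop("size must leave at least one measured metabolite")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(k), function(i) sample(measured, size))
}

#' Write a complete run directory
#'
#' One directory per run: per-solution reaction tables
#' (\code{solutions/solution_k.tsv}), per-solution variation tables
#' (\code{variations/solution_k.tsv}), the aggregated \code{occurrence.tsv},
#' the pathway-map export \code{escher_data.json} and a \code{run_log.txt}
#' echoing parameters and termination.
#'
#' @param ss a \linkS4class{SolutionSet}.
#' @param p the \linkS4class{ShiftProblem} that produced it.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeRunDirectory <- function(ss, p, dir) {
  net <- p@network
  dir.create(file.path(dir, "solutions"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "variations"), showWarnings = FALSE)
  org <- net@origin
  for (k in seq_along(ss@solutions)) {
    s <- ss@solutions[[k]]
    act <- which(s@support)
    tbl <- data.frame(reaction = org$origin[act],
                      direction = org$direction[act],
                      phi = unname(s@phi[act]), stringsAsFactors = FALSE)
    utils::write.table(tbl, file.path(dir, "solutions",
                                      sprintf("solution_%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    v <- s@predictedVariation
    vt <- data.frame(metabolite = names(v), variation = unname(v),
                     measured = p@bounds@measured, stringsAsFactors = FALSE)
    utils::write.table(vt, file.path(dir, "variations",
                                     sprintf("solution_%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tbl <- occurrenceTable(ss, net)
  utils::write.table(tbl, file.path(dir, "occurrence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  suppressWarnings(exportEscher(tbl, file.path(dir, "escher_data.json")))
  objs <- vapply(ss@solutions, function(s) s@objective, numeric(1))
  log_lines <- c(
    sprintf("solutions: %d", length(ss@solutions)),
    sprintf("termination: %s", ss@termination),
    sprintf("lambda: %g  theta: %g", p@lambda, p@theta),
    sprintf("mip_gap: %g  time_limit_s: %g  seed: %d  threads: %d",
            p@opts$mip_gap, p@opts$time_limit_s, p@opts$seed, p@opts$threads),
    sprintf("objective first/last: %.6f / %.6f",
            objs[1], objs[length(objs)]))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
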