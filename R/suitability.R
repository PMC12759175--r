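#' Binarization threshold maximizing sensitivity + specificity (maxSSS)
#'
#' Searches the observed suitability values for the threshold at which the
#' rule "present if suitability >= threshold" maximizes the sum of
#' sensitivity and specificity over the evaluation points. On ties the
#' smallest maximizing threshold is returned.
#'
#' @param suitabilities numeric suitability at the evaluation points
#' @param labels logical (or 0/1) presence labels, same length
#' @return list `threshold`, `sensitivity`, `specificity`
#' @examples
#' maxSssThreshold(c(0.9, 0.7, 0.6, 0.2), c(1, 1, 0, 0))$threshold  # 0.7
#' @export
maxSssThreshold <- function(suitabilities, labels) {
  labels <- as.logical(labels)
  stopifnot(length(suitabilities) == length(labels))
  if (!any(labels) || all(labels))
    stop("need at least one presence and one absence", call. = FALSE)
  cand <- sort(unique(suitabilities))
  pres <- suitabilities[labels]
  abse <- suitabilities[!labels]
  sens <- vapply(cand, function(t) mean(pres >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(abse < t), numeric(1))
  best <- which.max(sens + spec)  # which.max takes the first (smallest) tie
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best])
}

#' Majority-rule consensus of binary presence maps
#'
#' A unit (reach or grid cell) is considered occupied when strictly more
#' than half of the models predict presence.
#'
#' @param binary_maps logical/0-1 matrix, rows = units, columns = models;
#'   or a list of equal-length vectors (one per model)
#' @return logical vector over units
#' @export
consensusPresence <- function(binary_maps) {
  if (is.list(binary_maps) && !is.data.frame(binary_maps)) {
    len <- vapply(binary_maps, length, integer(1))
    if (length(unique(len)) != 1)
      stop("model maps have mismatched supports", call. = FALSE)
    nm <- lapply(binary_maps, names)
    if (!all(vapply(nm, identical, logical(1), nm[[1]])))
      stop("model maps have mismatched supports", call. = FALSE)
    binary_maps <- do.call(cbind, binary_maps)
  }
  m <- ncol(as.matrix(binary_maps))
  rowSums(as.matrix(binary_maps) > 0) > m / 2
}

#' Drop ensemble members with insufficient discrimination
#'
#' @param auc named numeric AUC per model
#' @param cutoff retain models with `AUC > cutoff` (default 0.8)
#' @return names (or indices) of the retained models
#' @export
aucFilter <- function(auc, cutoff = 0.8) {
  keep <- which(auc > cutoff)
  if (is.null(names(auc))) keep else names(auc)[keep]
}

#' Ensemble consensus suitability for one species
#'
#' Applies the ensemble rules in sequence: models with AUC <= `cutoff` are
#' dropped; the continuous consensus is the mean of the retained model
#' predictions; the binary consensus binarizes each retained model at its
#' own maxSSS threshold (from the supplied evaluation data) and takes the
#' strict-majority vote. Returns `NULL` with a warning when no model
#' survives the AUC filter (the species is excluded).
#'
#' @param predictions numeric matrix, units x models, in \[0, 1\]
#' @param auc numeric AUC per model (columns of `predictions`)
#' @param eval_suit,eval_labels per-model evaluation data for
#'   thresholding: either a matrix of suitabilities (points x models) with
#'   a shared label vector, or `NULL` to skip the binary consensus
#' @param cutoff AUC cutoff, default 0.8
#' @return list `continuous` (mean suitability per unit), `binary`
#'   (majority presence, or `NULL`), `retained` (model indices)
#' @export
consensusSuitability <- function(predictions, auc, eval_suit = NULL,
                                 eval_labels = NULL, cutoff = 0.8) {
  predictions <- as.matrix(predictions)
  stopifnot(ncol(predictions) == length(auc))
  keep <- which(unname(auc) > cutoff)
  if (length(keep) == 0) {
    warning("no model with AUC > ", cutoff, "; species excluded",
            call. = FALSE)
    return(NULL)
  }
  cont <- rowMeans(predictions[, keep, drop = FALSE])
  bin <- NULL
  if (!is.null(eval_suit)) {
    eval_suit <- as.matrix(eval_suit)
    thr <- vapply(keep, function(k)
      maxSssThreshold(eval_suit[, k], eval_labels)$threshold, numeric(1))
    binMaps <- sweep(predictions[, keep, drop = FALSE], 2, thr, `>=`)
    bin <- consensusPresence(binMaps)
  }
  list(continuous = cont, binary = bin, retained = keep)
}

#' Group-mean suitability layer
#'
#' Arithmetic mean of per-species suitabilities over the species of a
#' group (`combined` = all species), per reach.
#'
#' @param species_layers numeric matrix, reaches x species, in \[0, 1\]
#' @param members columns (names or indices) of the group's species;
#'   default all
#' @return named numeric vector over reaches
#' @export
groupMeanSuitability <- function(species_layers, members = NULL) {
  species_layers <- as.matrix(species_layers)
  if (is.null(members)) members <- seq_len(ncol(species_layers))
  if (length(members) == 0) stop("empty species group", call. = FALSE)
  rowMeans(species_layers[, members, drop = FALSE])
}

#' Project per-cell suitability onto river reaches
#'
#' Assigns each reach the length-weighted mean of the grid-cell values its
#' polyline geometry intersects, clipping each segment to the cell borders
#' of a regular, axis-aligned grid analytically.
#'
#' @param grid list with `origin` (x, y of the lower-left corner),
#'   `cellsize` (scalar), and `values` (numeric matrix; `values[i, j]` is
#'   the cell spanning `x` in `origin[1] + (j-1..j) * cellsize`, `y` in
#'   `origin[2] + (i-1..i) * cellsize`)
#' @param network a [RiverNetwork][RiverNetwork-class] whose reaches carry
#'   WKT LINESTRING geometry
#' @return named numeric vector of per-reach suitability
#' @export
cellsToReaches <- function(grid, network) {
  r <- network@reaches
  out <- stats::setNames(rep(NA_real_, nrow(r)), r$reach_id)
  for (k in seq_len(nrow(r))) {
    coords <- .parseLinestring(r$geometry[k])
    if (is.null(coords))
      stop("reach '", r$reach_id[k], "' has no geometry", call. = FALSE)
    wl <- .gridLengths(coords, grid)
    if (length(wl$len) == 0 || sum(wl$len) == 0)
      stop("reach '", r$reach_id[k], "' intersects no grid cell",
           call. = FALSE)
    out[k] <- sum(wl$len * wl$val) / sum(wl$len)
  }
  out
}

.parseLinestring <- function(wkt) {
  if (is.na(wkt) || !grepl("LINESTRING", wkt, ignore.case = TRUE))
    return(NULL)
  body <- sub(".*\\(", "", sub("\\).*", "", wkt))
  pts <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  do.call(rbind, lapply(pts, as.numeric))
}

# split every segment at grid lines; return per-piece lengths and cell values
.gridLengths <- function(coords, grid) {
  cs <- grid$cellsize
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  vals <- grid$values
  lens <- numeric(0); cellVal <- numeric(0)
  for (s in seq_len(nrow(coords) - 1)) {
    a <- coords[s, ]; b <- coords[s + 1, ]
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    segLen <- sqrt(dx^2 + dy^2)
    if (segLen == 0) next
    tcuts <- c(0, 1)
    for (d in 1:2) {
      lo <- min(a[d], b[d]); hi <- max(a[d], b[d])
      o <- grid$origin[d]
      ks <- seq(ceiling((lo - o) / cs), floor((hi - o) / cs))
      gl <- o + ks * cs
      gl <- gl[gl > lo & gl < hi]
      if (length(gl) > 0)
        tcuts <- c(tcuts, (gl - a[d]) / (b[d] - a[d]))
    }
    tcuts <- sort(unique(pmin(pmax(tcuts, 0), 1)))
    for (p in seq_len(length(tcuts) - 1)) {
      tm <- (tcuts[p] + tcuts[p + 1]) / 2
      mx <- a[1] + tm * dx; my <- a[2] + tm * dy
      j <- floor((mx - x0) / cs) + 1
      i <- floor((my - y0) / cs) + 1
      if (i < 1 || j < 1 || i > nrow(vals) || j > ncol(vals)) next
      lens <- c(lens, (tcuts[p + 1] - tcuts[p]) * segLen)
      cellVal <- c(cellVal, vals[i, j])
    }
  }
  list(len = lens, val = cellVal)
}
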