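#' Build a pixel graph from a binary skeleton image
#'
#' Foreground pixels (value 1) are connected under the 8-connectivity
#' criterion and traversed depth-first to label clusters.  To counter
#' oversampling of the one-pixel-wide centerline, a diagonal adjacency is
#' dropped whenever the two pixels also share an orthogonal foreground
#' neighbour (the diagonal step is then redundant with a two-step
#' orthogonal path); per-pixel degrees are counted on this reduced
#' adjacency, so a staircase line stays degree 2 throughout and loop
#' corners raise no spurious branches.
#'
#' @param image numeric or logical matrix containing only 0 and 1
#'   (background / skeleton).
#' @return object of class `skeleton_graph`: list with `image`, `pixels`
#'   (data frame `row`, `col`, `degree`, `cluster`), `n_clusters`, and the
#'   reduced `adjacency` (list of integer neighbour indices per pixel).
#' @export
build_skeleton_graph <- function(image) {
  if (!is.matrix(image)) stop("image must be a matrix")
  v <- as.numeric(image)
  if (!all(v %in% c(0, 1))) stop("image must be binary (0/1)")
  img <- matrix(v, nrow(image), ncol(image))
  fg <- which(img == 1)
  nr <- nrow(img); nc <- ncol(img)
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  off <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
               c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  at <- function(r, c) r >= 1L & r <= nr & c >= 1L & c <= nc &
    img[cbind(pmin(pmax(r, 1L), nr), pmin(pmax(c, 1L), nc))] == 1
  adjacency <- vector("list", length(fg))
  full_adj <- vector("list", length(fg))
  for (p in seq_along(fg)) {
    r <- rows[p]; c <- cols[p]
    nb <- integer(0); nb_full <- integer(0)
    for (k in seq_len(8L)) {
      rr <- r + off[k, 1L]; cc <- c + off[k, 2L]
      if (!at(rr, cc)) next
      q <- idx[rr, cc]
      nb_full <- c(nb_full, q)
      diagonal <- off[k, 1L] != 0L && off[k, 2L] != 0L
      if (diagonal && (at(r, cc) || at(rr, c))) next  # redundant diagonal
      nb <- c(nb, q)
    }
    adjacency[[p]] <- nb
    full_adj[[p]] <- nb_full
  }
  cluster <- dfs_label(full_adj, length(fg))
  pixels <- data.frame(row = rows, col = cols,
                       degree = lengths(adjacency), cluster = cluster)
  structure(list(image = img, pixels = pixels,
                 n_clusters = if (length(fg)) max(cluster) else 0L,
                 adjacency = adjacency),
            class = "skeleton_graph")
}

# iterative depth-first search labelling; visited pixels are excluded from
# further search
dfs_label <- function(adj, n) {
  label <- integer(n)
  current <- 0L
  for (start in seq_len(n)) {
    if (label[start] != 0L) next
    current <- current + 1L
    stack <- start
    label[start] <- current
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (q in adj[[p]]) {
        if (label[q] == 0L) {
          label[q] <- current
          stack <- c(stack, q)
        }
      }
    }
  }
  label
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d foreground pixels, %d clusters (%dx%d canvas)\n",
              nrow(x$pixels), x$n_clusters, nrow(x$image), ncol(x$image)))
  invisible(x)
}

#' Branch-point census of a skeleton graph
#'
#' Classifies logical nodes by degree.  Junction pixels (reduced degree of
#' 3 or more) that touch each other are contracted into a single logical
#' branch node whose degree is the number of distinct skeleton branches
#' leaving the contracted set; endpoint pixels (degree 1) are tips.  Also
#' reports the apparent degree-4 share of branching points and the
#' largest-cluster fraction of the foreground.
#'
#' @param graph a [build_skeleton_graph()] result.
#' @return object of class `branch_census`: list with `x1` (tips), `x3`,
#'   `x4` (apparent branch nodes of degree 3 and >= 4),
#'   `fraction_k4_apparent` (percent of branching points), `n_clusters`,
#'   `largest_cluster_fraction`, and `node_degrees` (integer vector of
#'   contracted branch-node degrees).
#' @export
degree_census <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  deg <- graph$pixels$degree
  junction <- which(deg >= 3L)
  node_degrees <- integer(0)
  if (length(junction) > 0L) {
    jset <- logical(nrow(graph$pixels))
    jset[junction] <- TRUE
    jadj <- lapply(junction, function(p)
      match(graph$adjacency[[p]][jset[graph$adjacency[[p]]]], junction))
    jlab <- dfs_label(jadj, length(junction))
    node_degrees <- vapply(seq_len(max(jlab)), function(g) {
      members <- junction[jlab == g]
      out <- unique(unlist(graph$adjacency[members]))
      length(setdiff(out, members))
    }, integer(1L))
  }
  x1 <- sum(deg == 1L)
  x3 <- sum(node_degrees == 3L)
  x4 <- sum(node_degrees >= 4L)
  csize <- tabulate(graph$pixels$cluster)
  structure(list(
    x1 = x1, x3 = x3, x4 = x4,
    fraction_k4_apparent = if (x3 + x4 > 0) 100 * x4 / (x3 + x4) else NA_real_,
    n_clusters = graph$n_clusters,
    largest_cluster_fraction = if (length(csize)) max(csize) / sum(csize) else NA_real_,
    node_degrees = node_degrees), class = "branch_census")
}

#' @export
print.branch_census <- function(x, ...) {
  cat(sprintf(
    "<branch_census> tips: %d, k=3: %d, apparent k>=4: %d (%.1f%% of branching points); %d clusters, largest holds %.1f%% of foreground\n",
    x$x1, x$x3, x$x4, x$fraction_k4_apparent, x$n_clusters,
    100 * x$largest_cluster_fraction))
  invisible(x)
}

#' Confocal-overlay correction of the branching-point census
#'
#' A confocal slice is about twice as thick as a mitochondrial tubule, so
#' unrelated organelles overlapping along the optical axis masquerade as
#' branch points.  Given the apparent degree-4 share of branching points
#' and the estimated artifact rates, the corrected degree-3 share of true
#' branching points is
#' `100 * t3 / (t3 + t4)` with
#' `t4 = frac_k4_apparent * (1 - artifact_rate_k4)` and
#' `t3 = (100 - frac_k4_apparent) * (1 - artifact_rate_k3)`.
#'
#' @param frac_k4_apparent apparent k = 4 share of branching points, in
#'   percent (0-100).
#' @param artifact_rate_k4 fraction of apparent k = 4 nodes caused by
#'   overlay, in `[0, 1]` (estimated default 0.80).
#' @param artifact_rate_k3 fraction of apparent k = 3 nodes caused by
#'   overlay, in `[0, 1]` (estimated default 0.07).
#' @return corrected degree-3 share of true branching points, in percent.
#' @examples
#' overlay_correction(17, 0.80, 0.07)  # ~96% of true branch points are k = 3
#' @export
overlay_correction <- function(frac_k4_apparent, artifact_rate_k4 = 0.80,
                               artifact_rate_k3 = 0.07) {
  if (frac_k4_apparent < 0 || frac_k4_apparent > 100)
    stop("frac_k4_apparent must be a percentage in [0, 100]")
  if (any(c(artifact_rate_k4, artifact_rate_k3) < 0) ||
      any(c(artifact_rate_k4, artifact_rate_k3) > 1))
    stop("artifact rates must be fractions in [0, 1]")
  t4 <- frac_k4_apparent * (1 - artifact_rate_k4)
  t3 <- (100 - frac_k4_apparent) * (1 - artifact_rate_k3)
  if (t3 + t4 == 0) return(NA_real_)
  100 * t3 / (t3 + t4)
}

#' Generate a synthetic skeleton image with known ground truth
#'
#' Rasterizes one-pixel-wide motifs onto a blank canvas: open segments
#' (straight strokes), T junctions (one degree-3 node), rectangular loops
#' (no tips, no branches), and deliberate crossings of two unrelated
#' strokes (one apparent degree-4 node each, emulating the confocal
#' overlay artifact).  Motifs are placed with a 2-pixel clearance so
#' 8-connectivity never merges them, and the exact census is returned with
#' the image.
#'
#' @param n_open,n_t,n_loop,n_cross motif counts.
#' @param canvas canvas side length in pixels (square).
#' @param seed integer seed, or `NULL`.
#' @param allow_overlap must be `TRUE` when `n_cross > 0`; crossing
#'   strokes are overlapping by construction and are rejected otherwise.
#' @return list with `image` (0/1 matrix) and `truth` (list `x1`, `x3`,
#'   `x4_apparent`, `n_clusters`).
#' @export
generate_synthetic_skeleton <- function(n_open = 3L, n_t = 2L, n_loop = 1L,
                                        n_cross = 0L, canvas = 128L,
                                        seed = NULL, allow_overlap = n_cross > 0L) {
  if (n_cross > 0L && !allow_overlap)
    stop("crossing strokes overlap; set allow_overlap = TRUE to request them")
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(0, canvas, canvas)
  occupied <- matrix(FALSE, canvas, canvas)  # includes 2-px clearance halo

  place <- function(stamp) {
    h <- nrow(stamp); w <- ncol(stamp)
    for (try in seq_len(400L)) {
      r0 <- sample.int(canvas - h - 3L, 1L) + 1L
      c0 <- sample.int(canvas - w - 3L, 1L) + 1L
      rr <- r0:(r0 + h - 1L); cc <- c0:(c0 + w - 1L)
      halo_r <- max(1L, r0 - 2L):min(canvas, r0 + h + 1L)
      halo_c <- max(1L, c0 - 2L):min(canvas, c0 + w + 1L)
      if (any(occupied[halo_r, halo_c])) next
      img[rr, cc] <<- pmax(img[rr, cc], stamp)
      occupied[halo_r, halo_c] <<- TRUE
      return(TRUE)
    }
    stop("could not place motif; enlarge the canvas or reduce motif counts")
  }

  stamp_open <- function() {
    len <- sample(5:14, 1L)
    ori <- sample(c("h", "v", "d"), 1L)
    switch(ori,
      h = matrix(1, 1L, len),
      v = matrix(1, len, 1L),
      d = diag(1, len, len))
  }
  stamp_t <- function() {
    arm <- sample(3:6, 1L)
    m <- matrix(0, arm + 1L, 2L * arm + 1L)
    m[1L, ] <- 1
    m[, arm + 1L] <- 1
    m
  }
  stamp_loop <- function() {
    h <- sample(5:10, 1L); w <- sample(5:10, 1L)
    m <- matrix(0, h, w)
    m[1L, ] <- 1; m[h, ] <- 1; m[, 1L] <- 1; m[, w] <- 1
    m
  }
  stamp_cross <- function() {
    arm <- sample(3:6, 1L)
    m <- matrix(0, 2L * arm + 1L, 2L * arm + 1L)
    m[arm + 1L, ] <- 1
    m[, arm + 1L] <- 1
    m
  }

  for (k in seq_len(n_open)) place(stamp_open())
  for (k in seq_len(n_t)) place(stamp_t())
  for (k in seq_len(n_loop)) place(stamp_loop())
  for (k in seq_len(n_cross)) place(stamp_cross())

  truth <- list(x1 = 2L * n_open + 3L * n_t + 4L * n_cross,
                x3 = n_t, x4_apparent = n_cross,
                n_clusters = n_open + n_t + n_loop + n_cross)
  list(image = img, truth = truth)
}

#' Read / write a binary skeleton image
#'
#' PNG or TIFF, chosen by file extension.  Images are binarized strictly:
#' any value other than 0 or 1 (after collapsing colour channels by
#' maximum) is an error on read.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param image 0/1 matrix (for writing).
#' @return `read_skeleton_image` returns a 0/1 matrix;
#'   `write_skeleton_image` returns `path` invisibly.
#' @export
read_skeleton_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1L, 2L), max)
  if (!all(arr %in% c(0, 1))) stop("image must be binary (0/1)")
  matrix(as.numeric(arr), nrow(arr), ncol(arr))
}

#' @rdname read_skeleton_image
#' @export
write_skeleton_image <- function(image, path) {
  if (!all(image %in% c(0, 1))) stop("image must be binary (0/1)")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path),
    stop("unsupported image format: ", ext))
  invisible(path)
}
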