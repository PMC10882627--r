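#' Electrode montage
#'
#' A montage binds channel labels to 2-D positions on the unit-disc head
#' (x: left to right, y: posterior to anterior) and carries a symmetric,
#' irreflexive adjacency relation between neighbouring electrodes, used by
#' the cluster-based permutation test.
#'
#' @param labels character vector of channel labels
#' @param positions numeric matrix (length(labels) x 2) of x/y coordinates
#' @param adjacency either `NULL` (derive from positions, see
#'   `neighbour_dist`) or a two-column character matrix of neighbour pairs
#' @param neighbour_dist electrodes closer than this are neighbours when
#'   adjacency is derived from positions
#' @return an object of class `montage`: list with `labels`, `positions`
#'   (rownames = labels) and `adjacency` (named list of neighbour labels)
#' @export
montage <- function(labels, positions, adjacency = NULL,
                    neighbour_dist = 0.63) {
  stopifnot(is.character(labels), length(labels) >= 1)
  positions <- as.matrix(positions)
  if (nrow(positions) != length(labels) || ncol(positions) != 2)
    stop("positions must be a length(labels) x 2 matrix")
  rownames(positions) <- labels
  colnames(positions) <- c("x", "y")
  adj <- stats::setNames(vector("list", length(labels)), labels)
  if (is.null(adjacency)) {
    d <- as.matrix(stats::dist(positions))
    for (l in labels) {
      nb <- labels[d[l, ] > 0 & d[l, ] < neighbour_dist]
      adj[[l]] <- nb
    }
  } else {
    adjacency <- as.matrix(adjacency)
    for (i in seq_len(nrow(adjacency))) {
      a <- adjacency[i, 1]; b <- adjacency[i, 2]
      if (a == b) stop("adjacency must be irreflexive")
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  structure(list(labels = labels, positions = positions, adjacency = adj),
            class = "montage")
}

#' Standard 19-channel 10-20 montage
#'
#' Schematic 2-D projection of the international 10-20 system (19 scalp
#' electrodes) with the outer ring on the unit circle and Cz at the origin.
#' Mastoid positions (M1, M2) are available via `include_mastoids` for
#' recordings that carry reference channels; mastoids take no part in
#' adjacency.
#'
#' @param include_mastoids also position M1/M2 just below the ears
#' @return a [montage]
#' @export
montage_1020 <- function(include_mastoids = FALSE) {
  deg <- function(a) a * pi / 180
  ring <- function(label, angle, r) c(r * cos(deg(angle)), r * sin(deg(angle)))
  pos <- rbind(
    Fp1 = ring("Fp1", 108, 1), Fp2 = ring("Fp2", 72, 1),
    F7  = ring("F7", 144, 1),  F8  = ring("F8", 36, 1),
    T3  = c(-1, 0),            T4  = c(1, 0),
    T5  = ring("T5", 216, 1),  T6  = ring("T6", 324, 1),
    O1  = ring("O1", 252, 1),  O2  = ring("O2", 288, 1),
    F3  = c(-0.42, 0.52),      F4  = c(0.42, 0.52),
    C3  = c(-0.5, 0),          C4  = c(0.5, 0),
    P3  = c(-0.42, -0.52),     P4  = c(0.42, -0.52),
    Fz  = c(0, 0.5),           Cz  = c(0, 0),
    Pz  = c(0, -0.5)
  )
  ord <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
           "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  pos <- pos[ord, ]
  m <- montage(ord, pos)
  if (include_mastoids) {
    lab <- c(m$labels, "M1", "M2")
    p2 <- rbind(m$positions, M1 = c(-1.1, -0.35), M2 = c(1.1, -0.35))
    adj <- m$adjacency
    adj$M1 <- character(0)
    adj$M2 <- character(0)
    m <- structure(list(labels = lab, positions = p2, adjacency = adj),
                   class = "montage")
  }
  m
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage>", length(x$labels), "electrodes;",
      sum(lengths(x$adjacency)) / 2, "neighbour pairs\n")
  invisible(x)
}

# adjacency as list of integer neighbour indices restricted to `labels`
adjacency_index <- function(mont, labels) {
  idx <- match(labels, mont$labels)
  if (anyNA(idx)) stop("montage does not cover channels: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  lapply(labels, function(l) {
    nb <- intersect(mont$adjacency[[l]], labels)
    match(nb, labels)
  })
}
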