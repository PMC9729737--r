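#' @keywords internal
"_PACKAGE"

#' Behaviour part names of the 24-h time-use composition
#'
#' The four mutually exclusive and exhaustive daily behaviours, in the
#' canonical order used throughout the package: sleep, sedentary behaviour
#' (`sb`), light physical activity (`lpa`) and moderate-to-vigorous physical
#' activity (`mvpa`).
#'
#' @return Character vector of length four.
#' @export
#' @examples
#' tu_parts()
tu_parts <- function() c("sleep", "sb", "lpa", "mvpa")

#' Minutes in a day
#' @return 1440.
#' @export
tu_total <- function() 1440

## Coerce a composition (vector or matrix/data.frame) to a numeric matrix
## with columns ordered as `parts`. Unnamed input is assumed to already be
## in `parts` order.
comp_matrix <- function(x, parts = tu_parts()) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (ncol(x) != length(parts))
    stop("composition must have ", length(parts), " parts, got ", ncol(x))
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), parts))
      stop("composition part names must be {", paste(parts, collapse = ", "),
           "}, got {", paste(colnames(x), collapse = ", "), "}")
    x <- x[, parts, drop = FALSE]
  } else {
    colnames(x) <- parts
  }
  storage.mode(x) <- "double"
  x
}

#' Close a composition to a fixed total
#'
#' Rescales the parts of one or more compositions so that each sums to
#' `total` (1440 min by default) without changing their ratios.
#'
#' @param x Numeric vector of part minutes, or a matrix/data.frame with one
#'   composition per row.
#' @param total Target row total, in the units of `x`.
#' @param parts Part names (used to order named input).
#' @return Object of the same shape as `x`, each composition summing to
#'   `total`.
#' @export
#' @examples
#' closure(c(sleep = 503, sb = 668, lpa = 178, mvpa = 89))
closure <- function(x, total = tu_total(), parts = tu_parts()) {
  vec <- !is.matrix(x) && !is.data.frame(x)
  m <- comp_matrix(x, parts)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all composition parts must be strictly positive and finite")
  m <- m * (total / rowSums(m))
  if (vec) m[1, ] else m
}

#' Sequential binary partition for pivot coordinates
#'
#' An ordered permutation of the four behaviours. The first element is the
#' pivot: the first ilr coordinate contrasts it against the geometric mean
#' of the remaining behaviours.
#'
#' @param first Behaviour to place first (the pivot).
#' @param parts Canonical part order.
#' @return Character permutation of `parts` with `first` first and the rest
#'   in canonical order.
#' @export
#' @examples
#' sbp_pivot("mvpa")
sbp_pivot <- function(first, parts = tu_parts()) {
  first <- match.arg(first, parts)
  c(first, setdiff(parts, first))
}

#' Orthonormal ilr basis of a sequential binary partition
#'
#' Builds the D x (D-1) contrast matrix `V` of pivot (ilr) coordinates for
#' the part order `sbp`, so that `z = log(x) %*% V` and
#' `clr(x) = z %*% t(V)`. Column `k` carries the normalising constant
#' `sqrt((D-k)/(D-k+1))`, weight 1 on part `k` and `-1/(D-k)` on the later
#' parts.
#'
#' @param sbp Ordered character vector of part names.
#' @return Matrix with rows named by `sbp` and columns `z1..z(D-1)`;
#'   columns are orthonormal and each sums to zero.
#' @export
ilr_basis <- function(sbp = tu_parts()) {
  D <- length(sbp)
  if (D < 2 || anyDuplicated(sbp)) stop("sbp must be >= 2 distinct parts")
  V <- matrix(0, D, D - 1, dimnames = list(sbp, paste0("z", seq_len(D - 1))))
  for (k in seq_len(D - 1)) {
    r <- D - k
    s <- sqrt(r / (r + 1))
    V[k, k] <- s
    V[(k + 1):D, k] <- -s / r
  }
  V
}

#' Isometric log-ratio (pivot) coordinates
#'
#' Maps strictly positive compositions to unconstrained real coordinates.
#' Under the default partition (sleep, SB, LPA, MVPA): `z1` is sleep vs the
#' geometric mean of the waking behaviours, `z2` is SB vs the two activity
#' intensities, `z3` is LPA vs MVPA. The transform is scale invariant, so
#' closure does not change the result.
#'
#' @param x Composition vector, or matrix with one composition per row.
#' @param sbp Sequential binary partition (ordered part names).
#' @return Numeric vector `c(z1, z2, z3)` or an n x 3 matrix.
#' @export
#' @examples
#' ilr_transform(c(sleep = 503, sb = 668, lpa = 178, mvpa = 89))
ilr_transform <- function(x, sbp = tu_parts()) {
  vec <- !is.matrix(x) && !is.data.frame(x)
  m <- comp_matrix(x, sbp)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("ilr requires strictly positive parts")
  z <- log(m) %*% ilr_basis(sbp)
  if (vec) z[1, ] else z
}

#' Inverse ilr transform
#'
#' Recovers the unique strictly positive composition (closed to `total`)
#' whose pivot coordinates equal `z`.
#'
#' @param z Numeric vector of length D-1, or an n x (D-1) matrix.
#' @param sbp Sequential binary partition used for the forward transform.
#' @param total Closure total in minutes.
#' @return Composition with parts in canonical [tu_parts()] order.
#' @export
ilr_inverse <- function(z, sbp = tu_parts(), total = tu_total()) {
  vec <- !is.matrix(z)
  if (vec) z <- matrix(z, nrow = 1)
  if (ncol(z) != length(sbp) - 1)
    stop("z must have ", length(sbp) - 1, " coordinates")
  if (any(!is.finite(z))) stop("ilr coordinates must be finite")
  x <- exp(z %*% t(ilr_basis(sbp)))
  colnames(x) <- sbp
  canon <- if (setequal(sbp, tu_parts())) tu_parts() else sbp
  x <- closure(x[, canon, drop = FALSE], total = total, parts = canon)
  if (vec) x[1, ] else x
}

#' Compositional mean
#'
#' The centre of a compositional sample: part-wise geometric means across
#' rows, closed to `total`. Identical (to numerical precision) to
#' `ilr_inverse(colMeans(ilr_transform(x)))`.
#'
#' @param x Matrix/data.frame of compositions, one per row.
#' @param total Closure total.
#' @return Named composition vector.
#' @export
compositional_mean <- function(x, total = tu_total()) {
  m <- comp_matrix(x)
  if (nrow(m) == 0) stop("need at least one composition")
  if (any(m <= 0)) stop("compositional mean requires strictly positive parts")
  closure(exp(colMeans(log(m))), total = total)
}

#' Amalgamate a four-part composition onto the ternary diagram
#'
#' Collapses LPA + MVPA into a single physical-activity part, expresses the
#' day as percentages of sleep, sedentary behaviour and physical activity,
#' and maps them to barycentric plotting coordinates on the 2-simplex
#' triangle (vertices: SB at (0,0), PA at (1,0), sleep at (1/2, sqrt(3)/2)).
#'
#' @param x Composition vector or matrix of compositions.
#' @return List with `percent` (sleep, sb, pa percentages summing to 100)
#'   and `xy` (barycentric coordinates), both matrices with one row per
#'   composition.
#' @export
amalgamate_to_ternary <- function(x) {
  m <- comp_matrix(x)
  m <- closure(m, total = 100)
  p3 <- cbind(sleep = m[, "sleep"], sb = m[, "sb"],
              pa = m[, "lpa"] + m[, "mvpa"])
  f <- p3 / 100
  verts <- rbind(sleep = c(0.5, sqrt(3) / 2), sb = c(0, 0), pa = c(1, 0))
  xy <- f[, rownames(verts), drop = FALSE] %*% verts
  colnames(xy) <- c("x", "y")
  list(percent = p3, xy = xy)
}
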