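#' GridMask specification
#'
#' Bundles the four numbers that define one GridMask lattice: the keep-ratio
#' `r`, the unit (tile) side length `d` in pixels, and the offsets
#' `delta_x`, `delta_y` of the first intact unit from the image boundary,
#' plus an optional rotation of the whole lattice.
#'
#' Within every `d` x `d` unit a square of side `round((1 - r) * d)` anchored
#' at the unit origin is dropped (set to 0); everything else is kept (1). The
#' asymptotic kept fraction is therefore `1 - (round((1 - r) * d) / d)^2`.
#'
#' @param r Keep-ratio in (0, 1]; `r = 1` drops nothing.
#' @param d Unit side length in pixels (integer >= 1).
#' @param delta_x,delta_y Integer offsets in `[0, d)` of the first intact
#'   unit from the left / top image boundary.
#' @param rotation_deg Rotation of the lattice in degrees (default 0).
#' @return An object of class `grid_spec`.
#' @seealso [generate_mask()], [apply_mask()], [gridmask_policy()]
#' @examples
#' spec <- grid_spec(r = 0.5, d = 4)
#' m <- generate_mask(spec, 8, 8)
#' mean(m) # kept fraction 0.75
#' @export
grid_spec <- function(r, d, delta_x = 0L, delta_y = 0L, rotation_deg = 0) {
  check_scalar_number(r, "r")
  if (r <= 0 || r > 1) stop_invalid("r must be in (0, 1]")
  check_scalar_number(d, "d", lo = 1, integer = TRUE)
  check_scalar_number(delta_x, "delta_x", lo = 0, hi = d - 1, integer = TRUE)
  check_scalar_number(delta_y, "delta_y", lo = 0, hi = d - 1, integer = TRUE)
  check_scalar_number(rotation_deg, "rotation_deg")
  structure(list(r = r, d = as.integer(d),
                 delta_x = as.integer(delta_x), delta_y = as.integer(delta_y),
                 rotation_deg = rotation_deg),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("GridMask spec: r = %g, d = %d, offset = (%d, %d), rotation = %g deg\n",
              x$r, x$d, x$delta_x, x$delta_y, x$rotation_deg))
  invisible(x)
}

# unrotated lattice on an H x W canvas; 0-based pixel (i, j) is dropped iff
# both ((i - dy) mod d) and ((j - dx) mod d) fall below the drop side s
gridmask_lattice <- function(r, d, dx, dy, height, width) {
  s <- round((1 - r) * d)
  i <- (seq_len(height) - 1L - dy) %% d
  j <- (seq_len(width) - 1L - dx) %% d
  drop <- outer(i < s, j < s, "&")
  m <- matrix(1L, height, width)
  m[drop] <- 0L
  m
}

#' Generate a GridMask binary mask
#'
#' Builds the `H x W` binary mask `M` for a [grid_spec()]: the plane is tiled
#' with `d x d` units whose first intact unit starts at
#' `(delta_y, delta_x)`; within each unit the square of side
#' `round((1 - r) * d)` at the unit origin is dropped. A non-zero
#' `rotation_deg` generates the lattice on an enlarged canvas
#' (side `ceiling(sqrt(2) * max(H, W))`), rotates it about its centre with
#' nearest-neighbour sampling so values stay exactly 0/1, and centre-crops,
#' leaving no unmasked corner artefacts.
#'
#' @param spec A [grid_spec()].
#' @param height,width Output mask size in pixels (>= 1).
#' @return An integer `height x width` matrix with entries in {0, 1}.
#' @examples
#' generate_mask(grid_spec(r = 0.5, d = 4), 8, 8)
#' @export
generate_mask <- function(spec, height, width) {
  if (!inherits(spec, "grid_spec")) stop_invalid("spec must be a grid_spec")
  check_scalar_number(height, "height", lo = 1, integer = TRUE)
  check_scalar_number(width, "width", lo = 1, integer = TRUE)
  rot <- spec$rotation_deg %% 360
  if (rot == 0)
    return(gridmask_lattice(spec$r, spec$d, spec$delta_x, spec$delta_y,
                            height, width))
  side <- ceiling(sqrt(2) * max(height, width))
  big <- gridmask_lattice(spec$r, spec$d, spec$delta_x, spec$delta_y,
                          side, side)
  rotated <- rotate_nn(big, rot)
  # centre crop to height x width
  r0 <- floor((side - height) / 2)
  c0 <- floor((side - width) / 2)
  rotated[r0 + seq_len(height), c0 + seq_len(width), drop = FALSE]
}

# nearest-neighbour rotation of a matrix about its centre; out-of-range
# sources wrap by reflection so the lattice statistics are preserved
rotate_nn <- function(m, angle_deg) {
  h <- nrow(m); w <- ncol(m)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ij <- expand.grid(i = seq_len(h), j = seq_len(w))
  dy <- ij$i - cy; dx <- ij$j - cx
  # inverse rotation: output pixel pulls from source coordinates
  si <- round(cy + cos(th) * dy + sin(th) * dx)
  sj <- round(cx - sin(th) * dy + cos(th) * dx)
  si <- pmin(pmax(si, 1L), h)
  sj <- pmin(pmax(sj, 1L), w)
  matrix(m[cbind(si, sj)], h, w)
}

#' Apply a binary mask to an image
#'
#' Element-wise product `X~ = X * M`: every channel of pixel `(i, j)` is
#' multiplied by `M[i, j]`. The input image is not modified.
#'
#' @param image An `H x W x C` array with finite intensities.
#' @param mask An `H x W` binary (0/1) matrix.
#' @return The masked `H x W x C` array.
#' @examples
#' img <- array(runif(8 * 8 * 3), c(8, 8, 3))
#' masked <- apply_mask(img, generate_mask(grid_spec(0.5, 4), 8, 8))
#' @export
apply_mask <- function(image, mask) {
  check_image(image)
  check_binary_mask(mask)
  d <- dim(image)
  if (nrow(mask) != d[1] || ncol(mask) != d[2])
    stop_invalid("mask dimensions must equal the image spatial dimensions")
  image * as.vector(mask) # recycles over channels (column-major)
}

#' GridMask sampling policy
#'
#' Training-time policy for drawing per-sample GridMask lattices: `d` is drawn
#' uniformly from `d_range`, the offsets uniformly from `[0, d)`, and the
#' rotation uniformly from `[0, 360)` when `rotate` is on.
#'
#' @param r Fixed keep-ratio in (0, 1].
#' @param d_range Inclusive integer interval for sampling `d`
#'   (lower bound >= 2).
#' @param apply_prob Probability in `[0, 1]` that GridMask is applied to a
#'   given sample.
#' @param rotate Draw a random lattice rotation per sample?
#' @param mask_labels Multiply the label mask by `M` as well? Off by default:
#'   the network is asked to predict tool pixels under the occlusion rather
#'   than to reproduce the holes.
#' @return An object of class `gridmask_policy`.
#' @export
gridmask_policy <- function(r = 0.6, d_range = c(8L, 24L), apply_prob = 0.5,
                            rotate = TRUE, mask_labels = FALSE) {
  check_scalar_number(r, "r")
  if (r <= 0 || r > 1) stop_invalid("r must be in (0, 1]")
  if (length(d_range) != 2L || any(d_range != round(d_range)))
    stop_invalid("d_range must be two integers")
  if (d_range[1] < 2 || d_range[2] < d_range[1])
    stop_invalid("d_range lower bound must be >= 2 and <= upper bound")
  check_scalar_number(apply_prob, "apply_prob", lo = 0, hi = 1)
  structure(list(r = r, d_range = as.integer(d_range),
                 apply_prob = apply_prob, rotate = isTRUE(rotate),
                 mask_labels = isTRUE(mask_labels)),
            class = "gridmask_policy")
}

#' Sample a GridMask specification from a policy
#'
#' Draws `d` uniformly from the policy's `d_range`, offsets uniformly from
#' `[0, d)`, and (when rotation is enabled) an angle uniformly from
#' `[0, 360)`. Uses the R random number stream, so results are reproducible
#' under `set.seed()`.
#'
#' @param policy A [gridmask_policy()].
#' @return A [grid_spec()].
#' @export
sample_spec <- function(policy) {
  if (!inherits(policy, "gridmask_policy"))
    stop_invalid("policy must be a gridmask_policy")
  d <- policy$d_range[1] + sample.int(diff(policy$d_range) + 1L, 1L) - 1L
  dx <- sample.int(d, 1L) - 1L
  dy <- sample.int(d, 1L) - 1L
  rot <- if (policy$rotate) runif(1, 0, 360) else 0
  grid_spec(r = policy$r, d = d, delta_x = dx, delta_y = dy,
            rotation_deg = rot)
}

#' Apply GridMask to one training sample
#'
#' With probability `apply_prob` samples a lattice from the policy, generates
#' the mask and multiplies the image by it; the label is multiplied only when
#' the policy's `mask_labels` flag is set. Otherwise image and label are
#' returned unchanged. GridMask is meant to run after intensity normalisation
#' and after the standard augmentations (see [apply_standard()]).
#'
#' @param image An `H x W x C` array in `[0, 1]`.
#' @param label An `H x W` binary label matrix aligned with `image`.
#' @param policy A [gridmask_policy()].
#' @return A list with elements `image` and `label`.
#' @export
augment_sample <- function(image, label, policy) {
  check_image(image)
  check_binary_mask(label, "label")
  d <- dim(image)
  if (nrow(label) != d[1] || ncol(label) != d[2])
    stop_invalid("label dimensions must equal the image spatial dimensions")
  if (!inherits(policy, "gridmask_policy"))
    stop_invalid("policy must be a gridmask_policy")
  if (policy$apply_prob == 0 || runif(1) >= policy$apply_prob)
    return(list(image = image, label = label))
  spec <- sample_spec(policy)
  m <- generate_mask(spec, d[1], d[2])
  out_label <- if (policy$mask_labels) label * m else label
  list(image = apply_mask(image, m), label = out_label)
}
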