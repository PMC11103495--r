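#' Rigid transform between two imaging rounds
#'
#' Represents the displacement of a moving image relative to a reference:
#' the mapping from reference pixel coordinates (0-based `(row, col)`,
#' pixel-centered) to moving-image coordinates is
#' `p_mov = R(theta) (p_ref - center) + center + (dy, dx)`.
#' [apply_transform()] resamples the moving image onto the reference grid
#' using this mapping.
#'
#' @param dy,dx translation in pixels (row, col).
#' @param theta rotation in radians about `center`.
#' @param score alignment confidence in \[0, 1\] (1 = perfect).
#' @param center rotation center `(row, col)`; `c(0, 0)` unless set by a
#'   fitting routine.
#' @return A list of class `rigid_transform`.
#' @export
rigid_transform <- function(dy = 0, dx = 0, theta = 0, score = NA_real_,
                            center = c(0, 0)) {
  structure(list(dy = dy, dx = dx, theta = theta, score = score,
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dy %.3f dx %.3f theta %.5f rad (score %.3f)\n",
              x$dy, x$dx, x$theta, x$score))
  invisible(x)
}

# (R, b) affine form of the reference->moving mapping: p_mov = R p_ref + b
tf_affine <- function(tf) {
  R <- matrix(c(cos(tf$theta), sin(tf$theta),
                -sin(tf$theta), cos(tf$theta)), 2, 2)
  b <- tf$center - R %*% tf$center + c(tf$dy, tf$dx)
  list(R = R, b = as.numeric(b))
}

affine_tf <- function(R, b, score = NA_real_) {
  rigid_transform(dy = b[1], dx = b[2], theta = atan2(R[2, 1], R[1, 1]),
                  score = score, center = c(0, 0))
}

#' Map points through a rigid transform
#' @param tf a [rigid_transform()].
#' @param pts n x 2 matrix of `(row, col)` coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(tf, pts) {
  a <- tf_affine(tf)
  pts <- as.matrix(pts)
  t(a$R %*% t(pts) + a$b)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return The inverse transform (same score).
#' @export
invert_transform <- function(tf) {
  a <- tf_affine(tf)
  Ri <- t(a$R)
  affine_tf(Ri, as.numeric(-Ri %*% a$b), score = tf$score)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first` and then `second` to
#' an image (i.e. the coordinate mapping `first(second(p))`). For two
#' round-to-round registrations A<-B and B<-C this gives the direct A<-C
#' transform.
#'
#' @param first,second [rigid_transform()]s.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(first, second) {
  a1 <- tf_affine(first); a2 <- tf_affine(second)
  affine_tf(a1$R %*% a2$R, as.numeric(a1$R %*% a2$b + a1$b))
}

# Bilinear rigid resampling core. Returns list(pixels, valid): out-of-field
# samples are filled with `fill` and flagged invalid.
warp_rigid <- function(img, dy, dx, theta = 0, center = NULL, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(center)) center <- c((nr - 1) / 2, (nc - 1) / 2)
  pr <- rep(0:(nr - 1), nc)
  pc <- rep(0:(nc - 1), each = nr)
  if (theta == 0) {
    ir <- pr + dy; ic <- pc + dx
  } else {
    ct <- cos(theta); st <- sin(theta)
    yr <- pr - center[1]; xc <- pc - center[2]
    ir <- ct * yr - st * xc + center[1] + dy
    ic <- st * yr + ct * xc + center[2] + dx
  }
  valid <- ir >= 0 & ir <= nr - 1 & ic >= 0 & ic <= nc - 1
  r0 <- pmin(pmax(floor(ir), 0), nr - 1)
  c0 <- pmin(pmax(floor(ic), 0), nc - 1)
  fr <- ir - r0; fc <- ic - c0
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  idx <- function(r, c) r + c * nr + 1
  v <- (1 - fr) * (1 - fc) * img[idx(r0, c0)] +
       (1 - fr) * fc       * img[idx(r0, c1)] +
       fr       * (1 - fc) * img[idx(r1, c0)] +
       fr       * fc       * img[idx(r1, c1)]
  v[!valid] <- fill
  list(pixels = matrix(v, nr, nc), valid = matrix(valid, nr, nc))
}

#' Resample an image through a rigid transform
#'
#' Bilinear resampling of the moving image onto the reference grid;
#' out-of-field pixels are filled with zero and flagged in the returned
#' validity mask.
#'
#' @param image [channel_image()] or numeric matrix (the moving image).
#' @param transform a [rigid_transform()].
#' @return A list: `pixels` (matrix aligned to the reference grid), `valid`
#'   (logical matrix).
#' @export
apply_transform <- function(image, transform) {
  img <- as_pixels(image)
  warp_rigid(img, transform$dy, transform$dx, transform$theta,
             center = if (transform$theta != 0) transform$center else NULL,
             fill = 0)
}

#' Align a moving channel and keep its metadata
#' @param ci a [channel_image()].
#' @param transform a [rigid_transform()].
#' @return A [channel_image()] with resampled pixels; the validity mask is
#'   attached as attribute `"valid"`.
#' @export
warp_channel <- function(ci, transform) {
  w <- apply_transform(ci, transform)
  out <- channel_image(w$pixels, ci$channel, ci$marker, ci$exposure_ms,
                       ci$pixel_size_um)
  attr(out, "valid") <- w$valid
  out
}

# Parabolic sub-pixel refinement of a 1D correlation peak (wrapped indices).
peak_subpixel <- function(vals, p, n) {
  vm <- vals[((p - 2) %% n) + 1]; v0 <- vals[p]; vp <- vals[(p %% n) + 1]
  den <- vm - 2 * v0 + vp
  if (abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (vm - vp) / den
  max(min(off, 0.5), -0.5)
}

#' Register two imaging rounds on their DAPI channels
#'
#' Phase correlation between the reference and moving DAPI images: the
#' normalized cross-power spectrum concentrates all alignment information in
#' a single correlation peak whose position is the rigid shift of the moving
#' round relative to the reference, refined to sub-pixel precision by
#' parabolic interpolation. The peak height (1 for a perfect shift, near 0
#' for unrelated images) is the confidence score; registration below
#' `min_score` raises an error so the round can be flagged.
#'
#' Rotation, off by default (serial rounds of one slide translate but rarely
#' rotate), is estimated by a coarse grid search over `theta_grid` when
#' `rotation = TRUE`.
#'
#' @param reference_dapi,moving_dapi [channel_image()]s or matrices of equal
#'   shape.
#' @param min_score confidence floor in \[0, 1\].
#' @param rotation estimate a rotation as well?
#' @param theta_grid candidate rotations (radians) searched when
#'   `rotation = TRUE`.
#' @return A [rigid_transform()] whose `(dy, dx)` is the displacement of the
#'   moving round relative to the reference; applying it to the moving round
#'   aligns it onto the reference grid.
#' @export
register_rounds <- function(reference_dapi, moving_dapi, min_score = 0.1,
                            rotation = FALSE,
                            theta_grid = seq(-0.1, 0.1, by = 0.01)) {
  ref <- as_pixels(reference_dapi); mov <- as_pixels(moving_dapi)
  if (!identical(dim(ref), dim(mov)))
    stop("reference and moving images differ in shape", call. = FALSE)
  if (!rotation) {
    est <- phase_correlate(ref, mov)
    tf <- rigid_transform(est$dy, est$dx, 0, score = est$score)
  } else {
    best <- NULL
    for (th in theta_grid) {
      unrot <- if (th == 0) mov
               else warp_rigid(mov, 0, 0, th)$pixels
      est <- phase_correlate(ref, unrot)
      if (is.null(best) || est$score > best$score)
        best <- list(score = est$score, dy = est$dy, dx = est$dx, theta = th)
    }
    # theta convention: mapping reference -> moving includes the rotation
    tf <- rigid_transform(best$dy, best$dx, best$theta, score = best$score,
                          center = c((nrow(ref) - 1) / 2, (ncol(ref) - 1) / 2))
  }
  if (is.na(tf$score) || tf$score < min_score)
    stop(sprintf(paste0("registration failed: confidence %.3f below floor ",
                        "%.3f (no common structure?)"), tf$score, min_score),
         call. = FALSE)
  tf
}

phase_correlate <- function(ref, mov) {
  ref <- ref - mean(ref); mov <- mov - mean(mov)
  fr <- stats::fft(ref); fm <- stats::fft(mov)
  cp <- fm * Conj(fr)
  mag <- Mod(cp)
  cp <- cp / (mag + 1e-12 * max(mag, .Machine$double.eps))
  r <- Re(stats::fft(cp, inverse = TRUE)) / length(cp)
  p <- which.max(r)
  nr <- nrow(ref); nc <- ncol(ref)
  pr <- ((p - 1) %% nr) + 1
  pc <- ((p - 1) %/% nr) + 1
  dy <- pr - 1; if (dy > nr / 2) dy <- dy - nr
  dx <- pc - 1; if (dx > nc / 2) dx <- dx - nc
  dy <- dy + peak_subpixel(r[, pc], pr, nr)
  dx <- dx + peak_subpixel(r[pr, ], pc, nc)
  list(dy = dy, dx = dx, score = max(min(r[p], 1), 0))
}

#' Least-squares rigid transform from control-point pairs
#'
#' Fits the rotation + translation minimizing the squared distance between
#' the transformed fixed points and their moving counterparts (orthogonal
#' Procrustes with reflection excluded), the programmatic counterpart of a
#' manual line-ROI alignment. The residual RMS (pixels) is reported in
#' `$rms`; `$score = 1 / (1 + rms)` so 1 means exact.
#'
#' @param fixed,moving n x 2 matrices of `(row, col)` coordinates, n >= 2,
#'   not all coincident.
#' @return A [rigid_transform()] mapping fixed (reference) coordinates to
#'   moving coordinates, ready for [apply_transform()] on the moving image.
#' @export
register_control_points <- function(fixed, moving) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (nrow(fixed) < 2L || nrow(moving) != nrow(fixed))
    stop("need >= 2 control-point pairs", call. = FALSE)
  fc <- colMeans(fixed); mc <- colMeans(moving)
  Fc <- sweep(fixed, 2, fc); Mc <- sweep(moving, 2, mc)
  if (max(abs(Fc)) < 1e-12 || max(abs(Mc)) < 1e-12)
    stop("control points are coincident; rotation is undetermined",
         call. = FALSE)
  H <- t(Fc) %*% Mc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  tf <- rigid_transform(dy = (mc - fc)[1], dx = (mc - fc)[2],
                        theta = atan2(R[2, 1], R[1, 1]), center = fc)
  pred <- transform_points(tf, fixed)
  rms <- sqrt(mean(rowSums((pred - moving)^2)))
  tf$score <- 1 / (1 + rms)
  tf$rms <- rms
  tf
}

#' Read / write rigid transforms as JSON
#' @param path file path.
#' @return `read_transform_json` returns a [rigid_transform()].
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$dy, x$dx, x$theta, x$score, x$center)
}

#' @rdname read_transform_json
#' @param tf a [rigid_transform()].
#' @export
write_transform_json <- function(tf, path) {
  jsonlite::write_json(unclass(tf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read control-point pairs from CSV
#'
#' Columns `fixed_x, fixed_y, moving_x, moving_y` (x = column, y = row).
#' @param path file path.
#' @return A list of `fixed` and `moving` n x 2 `(row, col)` matrices.
#' @export
read_control_points_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("fixed_x", "fixed_y", "moving_x", "moving_y")
  if (!all(need %in% names(df)))
    stop("control-point CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  list(fixed = cbind(df$fixed_y, df$fixed_x),
       moving = cbind(df$moving_y, df$moving_x))
}
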