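#' Double-pulse shadowgraph imaging setup
#'
#' Geometry and noise model of the synthetic shadowgraph imaging: a backlit
#' field of view in which droplets appear as dark disks on a bright noisy
#' background, exposed twice with a short pulse separation so that droplet
#' displacement between the frames yields the velocity V_0 = dh/dt.
#'
#' Defaults mirror a 10x long-distance objective: a 0.67 x 0.89 mm field of
#' view at 1 um/pixel, a pulse separation of 1 us and a focal-plane thickness
#' of 0.1 mm. Defocus blur is modelled as a Gaussian edge spread whose width
#' grows linearly with the distance from the focal plane and is independent
#' of droplet size (the circle of confusion is a property of the optics, not
#' of the particle).
#'
#' @param fov Field of view `c(width, height)` in m.
#' @param pixels Image size `c(width, height)` in pixels.
#' @param dt Pulse separation in s.
#' @param delta_f Focal-plane thickness delta_F in m.
#' @param background Background intensity level in [0, 1].
#' @param dark Intensity at the centre of an opaque in-focus droplet.
#' @param noise_sd Standard deviation of the additive pixel noise.
#' @param defocus_coef Blur sigma, in pixels, reached at depth |z| = delta_f.
#' @param aa_width Intrinsic edge width of an in-focus disk, in pixels.
#' @return An object of class `imaging_setup`; `px` holds the derived pixel
#'   pitch `c(x, y)` in m.
#' @examples
#' imaging_setup()
#' @export
imaging_setup <- function(fov = c(0.67e-3, 0.89e-3),
                          pixels = c(670L, 890L),
                          dt = 1e-6,
                          delta_f = 1e-4,
                          background = 0.85,
                          dark = 0.05,
                          noise_sd = 0.02,
                          defocus_coef = 1.5,
                          aa_width = 0.45) {
  stopifnot(length(fov) == 2, all(fov > 0),
            length(pixels) == 2, all(pixels >= 8),
            dt > 0, delta_f > 0,
            background > 0, background <= 1,
            dark >= 0, dark < background,
            noise_sd >= 0, defocus_coef > 0, aa_width > 0)
  structure(
    list(fov = fov, pixels = as.integer(pixels), dt = dt, delta_f = delta_f,
         background = background, dark = dark, noise_sd = noise_sd,
         defocus_coef = defocus_coef, aa_width = aa_width,
         px = fov / pixels),
    class = "imaging_setup"
  )
}

#' Ground-truth droplets for the image simulator
#'
#' @param x,y In-plane positions in m (x across the width, y down the
#'   height).
#' @param z Depth offsets from the focal plane in m.
#' @param D Droplet diameters in m, within the generation range
#'   0.5-120 um (slightly wider than the 1-100 um detection range).
#' @param vx,vy Velocity components in m/s; `vy > 0` is the downward spray
#'   direction.
#' @return A data.frame of class `ground_truth_droplets`.
#' @examples
#' ground_truth_droplets(x = 0.3e-3, y = 0.3e-3, z = 0, D = 20e-6, vy = 10)
#' @export
ground_truth_droplets <- function(x, y, z = 0, D, vx = 0, vy = 0) {
  n <- max(length(x), length(y), length(D))
  d <- data.frame(x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
                  D = rep_len(D, n), vx = rep_len(vx, n),
                  vy = rep_len(vy, n))
  if (any(d$D < 0.5e-6) || any(d$D > 120e-6)) {
    stop("ground-truth droplet diameters must lie in [0.5, 120] um",
         call. = FALSE)
  }
  class(d) <- c("ground_truth_droplets", "data.frame")
  d
}

# Draw one shadowgraph frame at time offset t (s). Dark disks are composited
# multiplicatively (absorption); the radial edge profile is a Gaussian CDF
# whose width combines the intrinsic (anti-aliasing) edge with defocus blur,
# which preserves the integrated intensity deficit of the sharp disk.
render_frame <- function(droplets, setup, t = 0) {
  nx <- setup$pixels[1]
  ny <- setup$pixels[2]
  img <- matrix(setup$background, nrow = ny, ncol = nx)
  opacity <- (setup$background - setup$dark) / setup$background
  for (k in seq_len(nrow(droplets))) {
    dk <- droplets[k, ]
    cx <- (dk$x + dk$vx * t) / setup$px[1] + 0.5
    cy <- (dk$y + dk$vy * t) / setup$px[2] + 0.5
    r <- dk$D / 2 / setup$px[1]
    sigma <- sqrt(setup$aa_width^2 +
                    (setup$defocus_coef * abs(dk$z) / setup$delta_f)^2)
    half <- ceiling(r + 4 * sigma + 1)
    j_lo <- max(1, floor(cx - half)); j_hi <- min(nx, ceiling(cx + half))
    i_lo <- max(1, floor(cy - half)); i_hi <- min(ny, ceiling(cy + half))
    if (j_lo > j_hi || i_lo > i_hi) next  # fully outside: clipped
    js <- j_lo:j_hi
    is <- i_lo:i_hi
    dx <- js - cx
    dy <- is - cy
    dist <- sqrt(outer(dy^2, dx^2, "+"))
    cover <- stats::pnorm((r - dist) / sigma)
    img[is, js] <- img[is, js] * (1 - opacity * cover)
  }
  img
}

#' Render a double-exposure shadowgraph image pair
#'
#' Draws the droplets as dark disks on a bright noisy background in two
#' frames separated by the pulse delay `setup$dt`; between the frames each
#' droplet translates by its velocity times `dt`. Out-of-focus droplets are
#' blurred according to their depth offset. Droplets (partially) outside the
#' field of view are silently clipped.
#'
#' @param droplets A [ground_truth_droplets()] data.frame (may have 0 rows).
#' @param setup An [imaging_setup()].
#' @param seed Integer seed for the pixel noise.
#' @return List with matrices `frame1` and `frame2` (rows = image height,
#'   values in [0, 1]).
#' @examples
#' d <- ground_truth_droplets(x = 0.3e-3, y = 0.3e-3, D = 20e-6, vy = 10)
#' pair <- render_pair(d, imaging_setup(), seed = 1)
#' @export
render_pair <- function(droplets, setup = imaging_setup(), seed = 1L) {
  stopifnot(inherits(setup, "imaging_setup"))
  if (is.null(droplets)) droplets <- ground_truth_droplets(
    x = numeric(0), y = numeric(0), D = numeric(0))
  with_seed(seed, {
    f1 <- render_frame(droplets, setup, t = 0)
    f2 <- render_frame(droplets, setup, t = setup$dt)
    n <- length(f1)
    f1 <- f1 + stats::rnorm(n, 0, setup$noise_sd)
    f2 <- f2 + stats::rnorm(n, 0, setup$noise_sd)
    list(frame1 = pmin(pmax(f1, 0), 1), frame2 = pmin(pmax(f2, 0), 1))
  })
}

# 8-connected component labelling of a logical matrix, BFS with vectorised
# frontier expansion. Returns a list of integer index vectors (column-major).
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  dark <- which(mask)
  if (length(dark) == 0) return(list())
  in_mask <- logical(nr * nc)
  in_mask[dark] <- TRUE
  visited <- logical(nr * nc)
  comps <- list()
  for (seed in dark) {
    if (visited[seed]) next
    comp <- integer(0)
    frontier <- seed
    visited[seed] <- TRUE
    while (length(frontier) > 0) {
      comp <- c(comp, frontier)
      rows <- (frontier - 1L) %% nr + 1L
      nb <- c(
        frontier[rows > 1L] - 1L, frontier[rows < nr] + 1L,
        frontier - nr, frontier + nr,
        frontier[rows > 1L] - 1L - nr, frontier[rows > 1L] - 1L + nr,
        frontier[rows < nr] + 1L - nr, frontier[rows < nr] + 1L + nr
      )
      nb <- nb[nb >= 1L & nb <= nr * nc]
      nb <- unique(nb[in_mask[nb] & !visited[nb]])
      visited[nb] <- TRUE
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' Detect droplets in a shadowgraph frame
#'
#' Finds sufficiently sharp dark disks: the frame is thresholded at half the
#' nominal shadow contrast, connected dark regions are labelled, and each
#' candidate is sized from its integrated intensity deficit (which is
#' invariant under defocus blur) with a small edge-width correction.
#' A sharpness score -- the maximum noise-smoothed intensity gradient across
#' the droplet edge, normalised by the shadow contrast -- gates out
#' out-of-focus droplets; detections outside the 1-100 um range or touching
#' the image border are discarded.
#'
#' @param image Numeric matrix in [0, 1] (one frame of [render_pair()]).
#' @param setup The [imaging_setup()] used to form the image.
#' @param sharpness_gate Minimum sharpness score; the default 0.25 rejects
#'   droplets beyond about one focal-plane thickness from focus.
#' @param frame Frame index stored with each detection.
#' @return data.frame of class `droplet_detections` with columns `x_px`,
#'   `y_px` (sub-pixel centre), `diameter` (m), `sharpness` and `frame`.
#'   Attribute `n_rejected` counts candidates removed by the gates.
#' @examples
#' d <- ground_truth_droplets(x = 0.3e-3, y = 0.3e-3, D = 20e-6, vy = 10)
#' pair <- render_pair(d, imaging_setup(), seed = 1)
#' detect_droplets(pair$frame1, imaging_setup())
#' @export
detect_droplets <- function(image, setup = imaging_setup(),
                            sharpness_gate = 0.25, frame = 1L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  nr <- nrow(image)
  nc <- ncol(image)
  bg <- stats::median(image)
  amp <- bg - setup$dark
  mask <- image < bg - 0.5 * amp
  comps <- label_components(mask)

  out <- list()
  n_rejected <- 0L
  for (comp in comps) {
    # single-pixel components are kept: the half-contrast threshold lies
    # ~20 noise sigmas below background, so they cannot be noise
    rows <- (comp - 1L) %% nr + 1L
    cols <- (comp - 1L) %/% nr + 1L
    pad <- 6L
    r1 <- min(rows) - pad; r2 <- max(rows) + pad
    c1 <- min(cols) - pad; c2 <- max(cols) + pad
    if (r1 < 1 || c1 < 1 || r2 > nr || c2 > nc) {
      n_rejected <- n_rejected + 1L
      next  # touches the border: size would be clipped
    }
    patch <- image[r1:r2, c1:c2]
    deficit <- pmax(bg - patch, 0)

    # sharpness: max gradient of the lightly smoothed patch, per pixel
    sm <- smooth3(patch)
    grad <- max(abs(diff(sm)), abs(t(diff(t(sm)))))
    sharpness <- grad / amp

    # edge-width estimate from the sharpness, used to debias the area
    s_clamped <- min(sharpness, 0.995)
    sigma_est <- 0.5 / stats::qnorm((1 + s_clamped) / 2)
    area_px <- sum(deficit) / amp
    r_px2 <- area_px / pi - sigma_est^2
    if (r_px2 <= 0.2) { n_rejected <- n_rejected + 1L; next }
    r_px <- sqrt(r_px2)
    diameter <- 2 * r_px * setup$px[1]

    w <- deficit
    x_px <- sum(w * col(patch)) / sum(w) + c1 - 1
    y_px <- sum(w * row(patch)) / sum(w) + r1 - 1

    if (sharpness < sharpness_gate ||
        diameter < 1e-6 || diameter > 100e-6) {
      n_rejected <- n_rejected + 1L
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      x_px = x_px, y_px = y_px, diameter = diameter,
      sharpness = sharpness, frame = frame
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(x_px = numeric(0), y_px = numeric(0), diameter = numeric(0),
               sharpness = numeric(0), frame = integer(0))
  attr(res, "n_rejected") <- n_rejected
  class(res) <- c("droplet_detections", "data.frame")
  res
}

# 3x3 binomial smoothing (separable 1/4, 1/2, 1/4), edges replicated.
smooth3 <- function(m) {
  pad_r <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  v <- (pad_r[seq_len(nrow(m)), , drop = FALSE] +
          2 * pad_r[seq_len(nrow(m)) + 1, , drop = FALSE] +
          pad_r[seq_len(nrow(m)) + 2, , drop = FALSE]) / 4
  pad_c <- cbind(v[, 1, drop = FALSE], v, v[, ncol(v), drop = FALSE])
  (pad_c[, seq_len(ncol(m)), drop = FALSE] +
      2 * pad_c[, seq_len(ncol(m)) + 1, drop = FALSE] +
      pad_c[, seq_len(ncol(m)) + 2, drop = FALSE]) / 4
}

#' Match detections across a frame pair and measure velocities
#'
#' Pairs the detections of the two exposures one-to-one and converts each
#' matched displacement into a velocity, V_0 = dh/dt. Candidate pairs must
#' move predominantly downward and less than the displacement cutoff;
#' among candidates, pairing greedily prefers small displacement and similar
#' diameter. Unmatched detections are dropped and counted.
#'
#' @param det1,det2 [detect_droplets()] results for frames 1 and 2.
#' @param dt Pulse separation in s (> 0).
#' @param setup The [imaging_setup()] (for the pixel pitch).
#' @param max_displacement_px Displacement cutoff in pixels.
#' @param max_updrift_px Largest allowed upward displacement in pixels.
#' @param diameter_weight Cost, in pixels of displacement, per pixel of
#'   diameter mismatch.
#' @return A [spray_sample()]-compatible data.frame with columns `D_0` (m,
#'   mean of the two diameter estimates), `V_0` (m/s), the frame-1 position
#'   (`x_px`, `y_px`), displacement components, and attribute `n_unmatched`.
#' @examples
#' d <- ground_truth_droplets(x = 0.3e-3, y = 0.3e-3, D = 20e-6, vy = 10)
#' st <- imaging_setup()
#' pair <- render_pair(d, st, seed = 1)
#' m <- match_droplets(detect_droplets(pair$frame1, st),
#'                     detect_droplets(pair$frame2, st, frame = 2L), st$dt, st)
#' m$V_0
#' @export
match_droplets <- function(det1, det2, dt, setup = imaging_setup(),
                           max_displacement_px = 60,
                           max_updrift_px = 2,
                           diameter_weight = 10) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  empty <- data.frame(D_0 = numeric(0), V_0 = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      dx_px = numeric(0), dy_px = numeric(0))
  if (nrow(det1) == 0 || nrow(det2) == 0) {
    attr(empty, "n_unmatched") <- nrow(det1) + nrow(det2)
    return(empty)
  }
  cand <- expand.grid(i = seq_len(nrow(det1)), j = seq_len(nrow(det2)))
  dx <- det2$x_px[cand$j] - det1$x_px[cand$i]
  dy <- det2$y_px[cand$j] - det1$y_px[cand$i]
  disp <- sqrt(dx^2 + dy^2)
  dD_px <- abs(det2$diameter[cand$j] - det1$diameter[cand$i]) / setup$px[1]
  ok <- disp <= max_displacement_px & dy >= -max_updrift_px
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) {
    attr(empty, "n_unmatched") <- nrow(det1) + nrow(det2)
    return(empty)
  }
  cost <- disp[ok] + diameter_weight * dD_px[ok]
  ord <- order(cost)
  used1 <- logical(nrow(det1))
  used2 <- logical(nrow(det2))
  keep <- integer(0)
  for (k in ord) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE
    used2[j] <- TRUE
    keep <- c(keep, k)
  }
  i <- cand$i[keep]; j <- cand$j[keep]
  dxk <- (det2$x_px[j] - det1$x_px[i]) * setup$px[1]
  dyk <- (det2$y_px[j] - det1$y_px[i]) * setup$px[2]
  res <- data.frame(
    D_0 = (det1$diameter[i] + det2$diameter[j]) / 2,
    V_0 = sqrt(dxk^2 + dyk^2) / dt,
    x_px = det1$x_px[i], y_px = det1$y_px[i],
    dx_px = dxk / setup$px[1], dy_px = dyk / setup$px[2]
  )
  attr(res, "n_unmatched") <- (nrow(det1) - length(keep)) +
    (nrow(det2) - length(keep))
  res
}

#' Characterize a spray from synthetic shadowgraph image pairs
#'
#' End-to-end measurement pipeline: for each image pair, droplets are drawn
#' from the synthetic spray law, placed in the measurement volume, rendered
#' as a double exposure, detected in both frames, matched, and measured.
#' The concatenated observations form a [spray_sample()] ready for
#' [predict_ensemble()].
#'
#' @param config A [spray_config()] giving the spray statistics.
#' @param setup An [imaging_setup()].
#' @param n_pairs Number of image pairs (>= 1); a real measurement uses 400.
#' @param seed Integer seed for droplet draws and pixel noise.
#' @param droplets_per_pair Mean number of droplets per pair (Poisson).
#' @param depth_range Droplets are placed uniformly within `+/- depth_range`
#'   of the focal plane, in units of the focal-plane thickness.
#' @param sharpness_gate Passed to [detect_droplets()].
#' @return A list: `sample` (the measured [spray_sample()]), `ground_truth`
#'   (data.frame of all generated droplets), `n_detected`, `n_unmatched`.
#' @examples
#' res <- characterize_spray(spray_preset("reference"), n_pairs = 3, seed = 1)
#' res$sample
#' @export
characterize_spray <- function(config = spray_config(),
                               setup = imaging_setup(),
                               n_pairs, seed = config$seed,
                               droplets_per_pair = 3,
                               depth_range = 1.5,
                               sharpness_gate = 0.25) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  n_pairs <- as.integer(n_pairs)

  with_seed(seed, {
    all_obs <- list()
    gt <- list()
    n_detected <- 0L
    n_unmatched <- 0L
    median_d <- config$d_ref * (config$p_ref / config$pressure)^config$d_exp
    v_mean <- config$v_coef * (config$pressure / config$p_ref)^config$v_exp *
      exp(-config$distance / config$decay_length)

    for (p in seq_len(n_pairs)) {
      nk <- stats::rpois(1, droplets_per_pair)
      if (nk == 0) next
      D <- stats::rlnorm(nk, log(median_d), config$sdlog)
      D <- pmin(pmax(D, 1e-6), 100e-6)
      V <- v_mean * (D / median_d)^config$size_vel_corr *
        (1 + stats::rnorm(nk, 0, config$noise))
      V <- pmax(V, 0)
      # keep the droplet and its displaced twin inside the frame
      margin <- D / 2 + 10e-6
      disp <- V * setup$dt
      x <- stats::runif(nk, margin, setup$fov[1] - margin)
      y <- stats::runif(nk, margin, pmax(margin + 1e-6,
                                         setup$fov[2] - margin - disp))
      z <- stats::runif(nk, -depth_range * setup$delta_f,
                        depth_range * setup$delta_f)
      drops <- ground_truth_droplets(x = x, y = y, z = z, D = D, vy = V)
      gt[[length(gt) + 1L]] <- cbind(drops, pair = p)

      f1 <- render_frame(drops, setup, t = 0)
      f2 <- render_frame(drops, setup, t = setup$dt)
      npx <- length(f1)
      f1 <- pmin(pmax(f1 + stats::rnorm(npx, 0, setup$noise_sd), 0), 1)
      f2 <- pmin(pmax(f2 + stats::rnorm(npx, 0, setup$noise_sd), 0), 1)

      d1 <- detect_droplets(f1, setup, sharpness_gate, frame = 1L)
      d2 <- detect_droplets(f2, setup, sharpness_gate, frame = 2L)
      n_detected <- n_detected + nrow(d1) + nrow(d2)
      m <- match_droplets(d1, d2, setup$dt, setup)
      n_unmatched <- n_unmatched + attr(m, "n_unmatched")
      if (nrow(m) > 0) all_obs[[length(all_obs) + 1L]] <- m
    }

    obs <- if (length(all_obs)) do.call(rbind, all_obs) else NULL
    if (is.null(obs) || nrow(obs) == 0) {
      stop("no droplets were detected and matched; ",
           "increase n_pairs or droplets_per_pair", call. = FALSE)
    }
    list(
      sample = spray_sample(D_0 = obs$D_0, V_0 = obs$V_0,
                            pressure = config$pressure,
                            distance = config$distance,
                            viscosity = config$viscosity,
                            label = sprintf("shadowgraph, %d pairs", n_pairs)),
      ground_truth = do.call(rbind, gt),
      n_detected = n_detected,
      n_unmatched = n_unmatched
    )
  })
}

#' Read and write greyscale PGM images
#'
#' Portable greymap I/O for the synthetic shadowgraph frames (ASCII "P2" or
#' binary "P5", 8- or 16-bit). Intensities map linearly between [0, 1] and
#' the integer range.
#'
#' @param path File path.
#' @param image Numeric matrix in [0, 1].
#' @param maxval Integer white level (255 or 65535).
#' @param ascii Write ASCII "P2" (default) or binary "P5".
#' @return `read_pgm()`: a numeric matrix in [0, 1]; `write_pgm()`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".pgm")
#' write_pgm(matrix(runif(12), 3, 4), f)
#' dim(read_pgm(f))
#' @export
write_pgm <- function(image, path, maxval = 255L, ascii = TRUE) {
  stopifnot(is.matrix(image), maxval %in% c(255L, 65535L))
  q <- round(pmin(pmax(image, 0), 1) * maxval)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
               con)
    write(t(q), file = con, ncolumns = ncol(image))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(image), nrow(image), maxval),
              con, eos = NULL)
    writeBin(as.integer(t(q)), con,
             size = if (maxval == 255L) 1L else 2L, endian = "big")
  }
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  tokens <- character(0)
  buf <- ""
  while (length(tokens) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("\\s", ch)) {
      if (nzchar(buf)) { tokens <- c(tokens, buf); buf <- "" }
    } else {
      buf <- paste0(buf, ch)
    }
  }
  dims <- as.integer(tokens[1:2])
  maxval <- as.integer(tokens[3])
  n <- dims[1] * dims[2]
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    readBin(con, "integer", n = n, size = if (maxval <= 255) 1L else 2L,
            signed = FALSE, endian = "big")
  }
  matrix(vals / maxval, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}
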