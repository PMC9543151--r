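# Spatiotemporal phase-shift mapping: standard-size estimation, landmark
# alignment into a normalized bilateral frame, mirrored control template
# maps, and per-cell phase shifts of delay explants against the template.
#
# Coordinate convention: midline x = 0, lateral positive/negative per lobe,
# ventral y = 0; the left lobe mirrors onto the right by x -> -x.

#' Standard SCN map size from a cohort of explants
#'
#' Per-axis mean bounding extent (width, height) across explants.
#'
#' @param explants list of [scn_explant()] objects (>= 1, each >= 3 cells).
#' @return named numeric `c(width, height)`.
#' @export
standardize_size <- function(explants) {
  if (length(explants) == 0) stop("no explants")
  sizes <- t(vapply(explants, function(e) {
    xs <- vapply(e$cells, `[[`, 0, "x")
    ys <- vapply(e$cells, `[[`, 0, "y")
    if (length(xs) < 3) stop("explant with < 3 cells")
    c(width = diff(range(xs)), height = diff(range(ys)))
  }, numeric(2)))
  colMeans(sizes)
}

#' Apply a known similarity transform to an explant (testing helper)
#'
#' Scales, rotates and translates all cell coordinates, landmarks and lobe
#' extents; useful for constructing alignment fixtures with known ground
#' truth.
#'
#' @param explant an [scn_explant()].
#' @param scale scalar or `c(sx, sy)`.
#' @param rotate_rad rotation angle (radians, counter-clockwise).
#' @param translate `c(dx, dy)`.
#' @return the transformed explant.
#' @export
transform_explant <- function(explant, scale = 1, rotate_rad = 0,
                              translate = c(0, 0)) {
  s <- rep(scale, length.out = 2)
  R <- matrix(c(cos(rotate_rad), sin(rotate_rad),
                -sin(rotate_rad), cos(rotate_rad)), 2, 2)
  fwd <- function(x, y) {
    p <- R %*% rbind(x * s[1], y * s[2])
    list(x = p[1, ] + translate[1], y = p[2, ] + translate[2])
  }
  explant$cells <- lapply(explant$cells, function(cell) {
    p <- fwd(cell$x, cell$y)
    cell$x <- p$x; cell$y <- p$y
    cell
  })
  for (nm in names(explant$landmarks)) {
    lm <- explant$landmarks[[nm]]
    p <- fwd(lm[1], lm[2])
    explant$landmarks[[nm]] <- c(p$x, p$y)
  }
  for (df_nm in c("metrics", "truth")) {
    if (!is.null(explant[[df_nm]])) {
      p <- fwd(explant[[df_nm]]$x, explant[[df_nm]]$y)
      explant[[df_nm]]$x <- p$x
      explant[[df_nm]]$y <- p$y
    }
  }
  if (!is.null(explant$lobe_extent)) {
    explant$lobe_extent <- explant$lobe_extent * s[1]
  }
  explant
}

#' Align an explant into the standard bilateral frame
#'
#' A similarity transform fixed by the two landmarks: the optic chiasm maps
#' to the origin and the third ventricle to `(0, height)`; this fixes the
#' translation, the rotation and the dorsoventral scale. Each lobe is then
#' scaled separately along the lateral axis so its extent maps to
#' `width / 2` (the lobe extent comes from explant metadata when present,
#' else from the outermost cell). Optional `check_landmarks` on the explant
#' (`list(list(at = c(x, y), expect = c(x, y)), ...)`) must map onto their
#' expected standard positions within `tolerance`, otherwise alignment fails.
#'
#' @param explant an [scn_explant()] with `landmarks$oc` and `landmarks$v3`.
#' @param standard named `c(width, height)` of the standard frame (the
#'   normalized frame is `c(2, 1)`).
#' @param tolerance landmark-check tolerance in standard units.
#' @return the aligned explant, with a `transform` element recording the
#'   per-lobe scales, rotation and translation.
#' @export
align_explant <- function(explant, standard = c(width = 2, height = 1),
                          tolerance = 0.05) {
  lm <- explant$landmarks
  if (is.null(lm$oc) || is.null(lm$v3)) stop("missing landmarks (oc, v3)")
  u <- c(lm$v3[1] - lm$oc[1], lm$v3[2] - lm$oc[2])
  len <- sqrt(sum(u^2))
  if (len == 0) stop("degenerate landmarks: oc and v3 coincide")
  theta <- atan2(u[1], u[2])   # rotate so v3 sits straight above oc
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  s_y <- unname(standard["height"]) / len
  base <- function(x, y) {
    p <- R %*% rbind(x - lm$oc[1], y - lm$oc[2])
    list(x = p[1, ], y = p[2, ])
  }
  xs <- vapply(explant$cells, `[[`, 0, "x")
  ys <- vapply(explant$cells, `[[`, 0, "y")
  b <- base(xs, ys)
  half_w <- unname(standard["width"]) / 2
  # metadata lobe extents are lateral lengths in explant units; the base
  # transform is rigid, so they carry over unchanged
  extents <- explant$lobe_extent
  ext_of <- function(side) {
    if (!is.null(extents)) return(unname(extents[side]))
    v <- if (side == "left") -b$x[b$x < 0] else b$x[b$x > 0]
    if (length(v) == 0) return(NA_real_)
    max(v)
  }
  e_l <- ext_of("left"); e_r <- ext_of("right")
  if (is.na(e_l)) e_l <- e_r
  if (is.na(e_r)) e_r <- e_l
  if (is.na(e_l) || e_l <= 0 || e_r <= 0) stop("cannot determine lobe extents")
  s_x <- c(left = half_w / e_l, right = half_w / e_r)
  apply_full <- function(x, y) {
    p <- base(x, y)
    sx <- ifelse(p$x < 0, s_x["left"], s_x["right"])
    list(x = unname(p$x * sx), y = unname(p$y * s_y))
  }
  if (!is.null(explant$check_landmarks)) {
    for (chk in explant$check_landmarks) {
      p <- apply_full(chk$at[1], chk$at[2])
      if (sqrt((p$x - chk$expect[1])^2 + (p$y - chk$expect[2])^2) > tolerance)
        stop("alignment error: landmark mismatch beyond tolerance")
    }
  }
  explant$cells <- lapply(explant$cells, function(cell) {
    p <- apply_full(cell$x, cell$y)
    cell$x <- p$x; cell$y <- p$y
    cell
  })
  for (df_nm in c("metrics", "truth")) {
    if (!is.null(explant[[df_nm]])) {
      p <- apply_full(explant[[df_nm]]$x, explant[[df_nm]]$y)
      explant[[df_nm]]$x <- p$x
      explant[[df_nm]]$y <- p$y
    }
  }
  explant$landmarks <- list(oc = c(0, 0),
                            v3 = c(0, unname(standard["height"])))
  explant$lobe_extent <- c(left = half_w, right = half_w)
  explant$transform <- list(rotation_rad = theta, scale_y = s_y,
                            scale_x = s_x,
                            translation = -unname(unlist(lm$oc)))
  explant
}

# snap a coordinate to the nearest grid node (spacing 1/grid_n)
snap_to_grid <- function(v, grid_n) round(v * grid_n) / grid_n

#' Build a control template map
#'
#' Cells of the aligned control explants are binned to the nearest node of a
#' discrete grid (default 40 nodes per lobe per axis over the standard
#' outline); overlapping contributions are averaged (cell-count weighted).
#' The map is then finalized by mirroring each lobe onto the other and
#' averaging coincident entries, yielding a mirror-symmetric map; grid nodes
#' inside the outline that received no entry are recorded as gaps.
#'
#' @param control_explants list of processed, aligned control
#'   [scn_explant()]s (per-cell peaks in `$metrics`).
#' @param region region label stored on the template.
#' @param grid_n grid nodes per lobe per axis.
#' @param use_truth take peak times from the simulation truth instead of the
#'   measured metrics (testing only).
#' @return an object of class `template_map`: `entries` (x, y, peak_h, n),
#'   `gaps` (x, y), `spacing`, `grid_n`, `region`.
#' @export
build_template <- function(control_explants, region = NULL, grid_n = 40,
                           use_truth = FALSE) {
  rows <- do.call(rbind, lapply(control_explants, function(e) {
    df <- if (use_truth) {
      data.frame(x = e$truth$x, y = e$truth$y, peak_h = e$truth$true_peak_h)
    } else {
      if (is.null(e$metrics)) stop("explant must be processed first")
      m <- e$metrics[e$metrics$included & !is.na(e$metrics$peak1_h), ]
      data.frame(x = m$x, y = m$y, peak_h = m$peak1_h)
    }
    df
  }))
  if (is.null(rows) || nrow(rows) == 0) stop("no cells to build template from")
  spacing <- 1 / grid_n
  rows$gx <- snap_to_grid(rows$x, grid_n)
  rows$gy <- snap_to_grid(rows$y, grid_n)
  # cells near the curved boundary can snap to a node just outside the
  # outline; reassign those to the nearest inside node so every template
  # entry lies inside the standard outline
  nodes_all <- expand.grid(x = seq(-1, 1, by = spacing),
                           y = seq(0, 1, by = spacing))
  nodes_in <- nodes_all[in_scn_outline(nodes_all$x, nodes_all$y), ]
  out <- !in_scn_outline(rows$gx, rows$gy)
  for (i in which(out)) {
    j <- which.min((nodes_in$x - rows$x[i])^2 + (nodes_in$y - rows$y[i])^2)
    rows$gx[i] <- nodes_in$x[j]
    rows$gy[i] <- nodes_in$y[j]
  }
  # canonicalize grid values so grouping and mirroring match exactly
  rows$gx <- snap_to_grid(rows$gx, grid_n)
  rows$gy <- snap_to_grid(rows$gy, grid_n)
  agg <- aggregate(cbind(sum_peak = peak_h, n = rep(1, nrow(rows))) ~ gx + gy,
                   data = transform(rows, peak_h = peak_h), FUN = sum)
  # mirror each lobe onto the other and merge coincident nodes
  mirrored <- agg
  mirrored$gx <- -mirrored$gx
  both <- rbind(agg, mirrored)
  fin <- aggregate(cbind(sum_peak, n) ~ gx + gy, data = both, FUN = sum)
  entries <- data.frame(x = fin$gx, y = fin$gy,
                        peak_h = fin$sum_peak / fin$n, n = fin$n)
  key <- function(x, y) paste(round(x * grid_n), round(y * grid_n))
  gaps <- nodes_in[!(key(nodes_in$x, nodes_in$y) %in%
                       key(entries$x, entries$y)), ]
  rownames(gaps) <- NULL
  structure(list(entries = entries, gaps = gaps, spacing = spacing,
                 grid_n = grid_n, region = region),
            class = "template_map")
}

#' @export
print.template_map <- function(x, ...) {
  cat(sprintf("<template_map %s: %d entries, %d gaps, spacing %.4f>\n",
              if (is.null(x$region)) "" else x$region,
              nrow(x$entries), nrow(x$gaps), x$spacing))
  invisible(x)
}

#' Per-cell phase shifts of a delay explant against a control template
#'
#' For each included cell, the nearest template entry within `match_radius`
#' grid units supplies the control peak time; the shift is
#' `cell peak - template peak` (positive = delayed). Cells whose
#' neighbourhood holds no template entry (gaps) are dropped and counted.
#'
#' @param delay_explant a processed, aligned [scn_explant()].
#' @param template a [build_template()] result.
#' @param match_radius matching radius in grid units.
#' @param use_truth take peak times from simulation truth (testing only).
#' @return list with `shifts` (data frame: cell_id, x, y, shift_h) and
#'   `n_dropped`.
#' @export
compute_cell_shifts <- function(delay_explant, template, match_radius = 1.5,
                                use_truth = FALSE) {
  if (nrow(template$entries) == 0) stop("template is empty")
  cells <- if (use_truth) {
    data.frame(cell_id = delay_explant$truth$cell_id,
               x = delay_explant$truth$x, y = delay_explant$truth$y,
               peak_h = delay_explant$truth$true_peak_h)
  } else {
    if (is.null(delay_explant$metrics))
      stop("explant must be processed first")
    m <- delay_explant$metrics
    m <- m[m$included & !is.na(m$peak1_h), ]
    data.frame(cell_id = m$cell_id, x = m$x, y = m$y, peak_h = m$peak1_h)
  }
  max_d <- match_radius * template$spacing
  ex <- template$entries$x
  ey <- template$entries$y
  out <- vector("list", nrow(cells))
  n_dropped <- 0L
  for (i in seq_len(nrow(cells))) {
    d2 <- (ex - cells$x[i])^2 + (ey - cells$y[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_d) {
      out[[i]] <- data.frame(cell_id = cells$cell_id[i], x = cells$x[i],
                             y = cells$y[i],
                             shift_h = cells$peak_h[i] - template$entries$peak_h[j],
                             stringsAsFactors = FALSE)
    } else {
      n_dropped <- n_dropped + 1L
    }
  }
  shifts <- do.call(rbind, out)
  if (is.null(shifts))
    shifts <- data.frame(cell_id = character(0), x = numeric(0),
                         y = numeric(0), shift_h = numeric(0))
  rownames(shifts) <- NULL
  list(shifts = shifts, n_dropped = n_dropped)
}
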