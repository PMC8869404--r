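#' Parameters of a synthetic microglial phenotype
#'
#' Describes the random-walk branch model used by [simulate_cell_mask()]:
#' a filled soma disc from which `n_primary_branches` processes grow as
#' persistent random walks (per-step heading jitter
#' `tortuosity_sd_deg`), with optional one-level secondary branching.
#' Two presets bracket the biology: `"ramified"` (surveillant-like:
#' many long thin processes) and `"activated"` (de-ramified/compact:
#' few short thick processes, larger soma).
#'
#' @param soma_radius_px soma radius in pixels (> 0).
#' @param n_primary_branches number of primary processes (>= 0).
#' @param branch_length_mean_px,branch_length_sd_px branch length
#'   distribution in pixels (drawn normal, truncated to
#'   `[1, mean + 3 sd]`).
#' @param secondary_branch_prob probability that a primary process
#'   spawns one secondary branch (half-length).
#' @param tortuosity_sd_deg per-step heading jitter in degrees (>= 0).
#' @param process_thickness_px process thickness in pixels (>= 1).
#' @param seed integer seed; identical params + seed give a
#'   bit-identical mask.
#' @param label phenotype label recorded in the simulation truth.
#' @return list of class `cell_phenotype_params`.
#' @export
cell_phenotype_params <- function(soma_radius_px = 7,
                                  n_primary_branches = 5L,
                                  branch_length_mean_px = 40,
                                  branch_length_sd_px = 8,
                                  secondary_branch_prob = 0.3,
                                  tortuosity_sd_deg = 10,
                                  process_thickness_px = 1L,
                                  seed = 1L,
                                  label = "custom") {
  gp_assert(is_scalar_num(soma_radius_px) && soma_radius_px > 0,
            "soma_radius_px must be > 0")
  gp_assert(is_scalar_num(n_primary_branches) && n_primary_branches >= 0,
            "n_primary_branches must be >= 0")
  gp_assert(branch_length_mean_px > 0 && branch_length_sd_px > 0,
            "branch lengths must be > 0")
  gp_assert(secondary_branch_prob >= 0 && secondary_branch_prob <= 1,
            "secondary_branch_prob must be in [0, 1]")
  gp_assert(tortuosity_sd_deg >= 0, "tortuosity_sd_deg must be >= 0")
  gp_assert(is_scalar_num(process_thickness_px) && process_thickness_px >= 1,
            "process_thickness_px must be >= 1")
  structure(
    list(
      soma_radius_px = soma_radius_px,
      n_primary_branches = as.integer(n_primary_branches),
      branch_length_mean_px = branch_length_mean_px,
      branch_length_sd_px = branch_length_sd_px,
      secondary_branch_prob = secondary_branch_prob,
      tortuosity_sd_deg = tortuosity_sd_deg,
      process_thickness_px = as.integer(process_thickness_px),
      seed = as.integer(seed),
      label = label
    ),
    class = "cell_phenotype_params"
  )
}

#' @rdname cell_phenotype_params
#' @param preset `"ramified"` or `"activated"`.
#' @param ... overrides passed to [cell_phenotype_params()].
#' @export
phenotype_preset <- function(preset = c("ramified", "activated"), seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    ramified = list(
      soma_radius_px = 7, n_primary_branches = 6L,
      branch_length_mean_px = 60, branch_length_sd_px = 10,
      secondary_branch_prob = 0.5, tortuosity_sd_deg = 12,
      process_thickness_px = 1L, label = "ramified"
    ),
    activated = list(
      soma_radius_px = 11, n_primary_branches = 2L,
      branch_length_mean_px = 15, branch_length_sd_px = 5,
      secondary_branch_prob = 0.1, tortuosity_sd_deg = 12,
      process_thickness_px = 3L, label = "activated"
    )
  )
  do.call(cell_phenotype_params, modifyList(base, c(list(seed = seed), list(...))))
}

# half-extent (in px) a cell drawn with these params may need
required_half_extent <- function(params) {
  if (params$n_primary_branches == 0L) {
    return(ceiling(params$soma_radius_px + 2))
  }
  reach <- params$branch_length_mean_px + 3 * params$branch_length_sd_px
  secondary <- if (params$secondary_branch_prob > 0) 0.5 * reach else 0
  ceiling(params$soma_radius_px + reach + secondary +
            params$process_thickness_px / 2 + 2)
}

# stamp a filled disc of radius r at floating-point centre (r0, c0)
stamp_disc <- function(m, r0, c0, rad) {
  rr <- max(1L, floor(r0 - rad)):min(nrow(m), ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(ncol(m), ceiling(c0 + rad))
  if (length(rr) == 0L || length(cc) == 0L) return(m)
  sub <- outer(rr - r0, cc - c0, function(a, b) a^2 + b^2) <= rad^2 + 1e-9
  m[rr, cc] <- m[rr, cc] | sub
  m
}

#' Simulate a single-cell microglia mask
#'
#' Draws a soma disc plus random-walk processes on a square canvas and
#' returns the binary mask together with its ground truth (phenotype
#' label and generator parameters). Deterministic given
#' `params$seed`.
#'
#' @param params a [cell_phenotype_params()] (or preset).
#' @param canvas integer side length of the square canvas, or a
#'   length-2 vector (rows, cols).
#' @param calibration micrometres per pixel of the generated mask.
#' @return list with `mask` (a [cell_mask()]) and `truth` (list:
#'   `label`, `params`).
#' @export
simulate_cell_mask <- function(params, canvas = 256L, calibration = 0.31) {
  gp_assert(inherits(params, "cell_phenotype_params"),
            "params must be a cell_phenotype_params object")
  if (length(canvas) == 1L) canvas <- c(canvas, canvas)
  canvas <- as.integer(canvas)
  half <- floor(min(canvas) / 2) - 1L
  need <- required_half_extent(params)
  if (half < need) {
    gp_stop(
      sprintf(paste0(
        "canvas too small: half-extent %d px available, %d px required ",
        "(soma + branch reach + secondary allowance + thickness margin); ",
        "use a canvas of at least %d px"), half, need, 2L * (need + 1L)),
      "gp_canvas_error"
    )
  }
  ctr <- (canvas + 1) / 2

  m <- with_seed(params$seed, {
    m <- matrix(FALSE, canvas[1], canvas[2])
    m <- stamp_disc(m, ctr[1], ctr[2], params$soma_radius_px)
    nb <- params$n_primary_branches
    if (nb > 0L) {
      base_angles <- (seq_len(nb) - 1) * 2 * pi / nb + runif(1, 0, 2 * pi)
      thick_rad <- params$process_thickness_px / 2
      reach_cap <- params$branch_length_mean_px + 3 * params$branch_length_sd_px
      grow <- function(m, r0, c0, angle, len) {
        pos <- c(r0, c0)
        heading <- angle
        for (s in seq_len(max(1L, round(len)))) {
          heading <- heading + rnorm(1, 0, params$tortuosity_sd_deg * pi / 180)
          pos <- pos + c(sin(heading), cos(heading))
          # floor of 0.75 px: a thinner stamp can fall between the four
          # nearest pixel centres (max distance sqrt(2)/2) and break the
          # 8-connectivity contract
          m <- stamp_disc(m, pos[1], pos[2], max(0.75, thick_rad))
        }
        list(m = m, end = pos, heading = heading)
      }
      for (b in seq_len(nb)) {
        len <- min(max(1, rnorm(1, params$branch_length_mean_px,
                                params$branch_length_sd_px)), reach_cap)
        ang <- base_angles[b]
        start <- ctr + (params$soma_radius_px - 0.5) * c(sin(ang), cos(ang))
        g <- grow(m, start[1], start[2], ang, len)
        m <- g$m
        if (runif(1) < params$secondary_branch_prob) {
          frac <- runif(1, 0.3, 0.8)
          # branch point part-way along: re-grow is approximated by
          # spawning from the primary tip direction at the end point,
          # deflected +/- 30-60 degrees, at half length
          dev <- sample(c(-1, 1), 1) * runif(1, pi / 6, pi / 3)
          g2 <- grow(m, g$end[1], g$end[2], g$heading + dev, len * 0.5 * frac)
          m <- g2$m
        }
      }
    }
    m
  })
  gp_assert(n_components(m) == 1L,
            "generated mask unexpectedly has more than one component")
  list(
    mask = cell_mask(m, calibration = calibration),
    truth = list(label = params$label, params = params)
  )
}
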