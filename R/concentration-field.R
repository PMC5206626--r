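# Reconstruction of daily reach-scale CH4 and CO2 concentrations from sparse
# spatial surveys and temporally resolved anchor stations, plus sensor-series
# cleaning.
#
# The method assumes the concentration field is separable into a static
# spatial pattern times an anchor time series: spatial surveys fix per-reach
# ratios relative to the anchors, and the anchors carry the temporal signal.

#' Despike a sensor concentration series
#'
#' Removes condensation artefacts from high-frequency sensor data: a value is
#' removed when it deviates by more than `threshold` (default 20 %) from the
#' mean of the 12-hour window before it AND from the mean of the 12-hour
#' window after it. At the series ends, where only one window exists, that
#' single window decides. An empty series is returned unchanged.
#'
#' @param series Data frame with columns `time` (POSIXct, or numeric hours)
#'   strictly increasing, and `value` (> 0).
#' @param threshold Relative deviation triggering removal (default 0.2).
#' @param window_h Window length on each side (hours, default 12).
#' @return The filtered data frame (rows failing the rule removed), with the
#'   number of removed rows in attribute `n_removed`.
#' @export
despike_sensor <- function(series, threshold = 0.2, window_h = 12) {
  required <- c("time", "value")
  missing_cols <- setdiff(required, names(series))
  if (length(missing_cols)) {
    stop("sensor series is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(series) == 0) {
    attr(series, "n_removed") <- 0L
    return(series)
  }
  tt <- if (inherits(series$time, "POSIXct")) {
    as.numeric(series$time) / 3600
  } else {
    as.numeric(series$time)
  }
  if (any(diff(tt) <= 0)) {
    stop("sensor timestamps must be strictly increasing", call. = FALSE)
  }
  v <- series$value
  n <- length(v)
  remove <- logical(n)
  for (i in seq_len(n)) {
    before <- v[tt >= tt[i] - window_h & tt < tt[i]]
    after <- v[tt > tt[i] & tt <= tt[i] + window_h]
    dev_b <- length(before) > 0 &&
      abs(v[i] - mean(before)) > threshold * mean(before)
    dev_a <- length(after) > 0 &&
      abs(v[i] - mean(after)) > threshold * mean(after)
    remove[i] <- if (length(before) && length(after)) {
      dev_b && dev_a
    } else if (length(before)) {
      dev_b
    } else if (length(after)) {
      dev_a
    } else {
      FALSE
    }
  }
  out <- series[!remove, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(remove)
  out
}

# Topological order of branches: tributaries before the branch they feed.
# topology: data frame (branch_id, downstream_id), NA downstream = outlet.
.topo_order <- function(topology) {
  ids <- topology$branch_id
  done <- character(0)
  while (length(done) < length(ids)) {
    ready <- vapply(ids, function(b) {
      if (b %in% done) return(FALSE)
      ups <- ids[!is.na(topology$downstream_id) & topology$downstream_id == b]
      all(ups %in% done)
    }, logical(1))
    if (!any(ready)) stop("topology contains a cycle", call. = FALSE)
    done <- c(done, ids[ready])
  }
  done
}

# Downstream chain of a branch: c(branch, its downstream, ..., root).
.branch_chain <- function(branch, topology) {
  chain <- branch
  repeat {
    dn <- topology$downstream_id[topology$branch_id == chain[length(chain)]]
    if (length(dn) != 1 || is.na(dn)) break
    chain <- c(chain, dn)
  }
  chain
}

#' Along-network distance between two points
#'
#' Distance along the channel between points given as (branch, distance from
#' the branch head). Branches form a tree in which every tributary joins the
#' head of its downstream branch, so two points connect through the first
#' branch common to their downstream chains.
#'
#' @param branch_a,x_a,branch_b,x_b Branch ids and along-branch positions
#'   (m) of the two points.
#' @param topology Data frame `branch_id`, `downstream_id` (NA at the
#'   outlet).
#' @param branch_lengths Named numeric vector of branch lengths (m).
#' @return Distance (m).
#' @export
network_distance <- function(branch_a, x_a, branch_b, x_b, topology,
                             branch_lengths) {
  if (branch_a == branch_b) return(abs(x_a - x_b))
  chain_a <- .branch_chain(branch_a, topology)
  chain_b <- .branch_chain(branch_b, topology)
  common <- intersect(chain_a, chain_b)
  if (!length(common)) stop("points are not connected", call. = FALSE)
  c0 <- common[1]
  # distance travelled from a point to the head of branch `to` along a chain
  entry <- function(chain, x, to) {
    i <- match(to, chain)
    d <- branch_lengths[[chain[1]]] - x
    if (i > 2) d <- d + sum(vapply(chain[2:(i - 1)],
                                   function(b) branch_lengths[[b]],
                                   numeric(1)))
    d
  }
  if (c0 == branch_b) {
    entry(chain_a, x_a, c0) + x_b
  } else if (c0 == branch_a) {
    entry(chain_b, x_b, c0) + x_a
  } else {
    entry(chain_a, x_a, c0) + entry(chain_b, x_b, c0)
  }
}

.branch_meta <- function(reaches) {
  sp <- split(reaches, reaches$branch_id)
  data.frame(
    branch_id = names(sp),
    length_m = vapply(sp, function(d) max(d$end_m), numeric(1)),
    end_drainage_km2 = vapply(sp, function(d) d$drainage_km2[which.max(d$end_m)],
                              numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Interpolate a spatial concentration survey onto the reaches
#'
#' Assigns a concentration to every reach midpoint from one survey date:
#' linear in along-channel distance between bracketing samples on the same
#' branch, constant (nearest-sample) extrapolation beyond the terminal
#' samples. At a confluence the downstream branch starts from the
#' drainage-area-weighted mean of the merging branch endpoint values
#' (discharge-weighted under the D = bA scaling, so the choice is
#' mass-consistent). A headwater branch without any sample inherits the value
#' at the head of its downstream branch, with a warning.
#'
#' @param survey Data frame with columns `branch_id`, `distance_m`, `conc`
#'   (one survey date; > 0).
#' @param reaches Reach table from [discretize()].
#' @param topology Data frame `branch_id`, `downstream_id`.
#' @return Data frame `reach_id`, `conc`.
#' @export
spatial_interpolate <- function(survey, reaches, topology) {
  if (nrow(survey) == 0) stop("survey has no samples", call. = FALSE)
  if (any(survey$conc <= 0)) {
    stop("survey concentrations must be positive (all observations in this",
         " system are supersaturated)", call. = FALSE)
  }
  meta <- .branch_meta(reaches)
  ord <- .topo_order(topology)
  end_val <- stats::setNames(rep(NA_real_, nrow(meta)), meta$branch_id)
  reach_val <- stats::setNames(rep(NA_real_, nrow(reaches)), reaches$reach_id)
  head_val <- stats::setNames(rep(NA_real_, nrow(meta)), meta$branch_id)
  deferred <- character(0)

  for (b in ord) {
    len_b <- meta$length_m[meta$branch_id == b]
    s <- survey[survey$branch_id == b, , drop = FALSE]
    nodes_x <- s$distance_m
    nodes_v <- s$conc
    ups <- topology$branch_id[!is.na(topology$downstream_id) &
                                topology$downstream_id == b]
    ups_ok <- ups[!is.na(end_val[ups])]
    if (length(ups_ok)) {
      w <- meta$end_drainage_km2[match(ups_ok, meta$branch_id)]
      nodes_x <- c(0, nodes_x)
      nodes_v <- c(stats::weighted.mean(end_val[ups_ok], w), nodes_v)
    }
    rr <- reaches[reaches$branch_id == b, , drop = FALSE]
    if (length(nodes_x) >= 2) {
      o <- order(nodes_x)
      vals <- stats::approx(nodes_x[o], nodes_v[o], xout = rr$midpoint_m,
                            rule = 2, ties = mean)$y
      ev <- stats::approx(nodes_x[o], nodes_v[o], xout = len_b,
                          rule = 2, ties = mean)$y
    } else if (length(nodes_x) == 1) {
      vals <- rep(nodes_v, nrow(rr))
      ev <- nodes_v
    } else {
      deferred <- c(deferred, b)
      next
    }
    reach_val[rr$reach_id] <- vals
    end_val[b] <- ev
    head_val[b] <- if (length(nodes_x)) nodes_v[which.min(nodes_x)] else NA
  }

  # unsampled headwater branches: fill from the head of the downstream branch
  if (length(deferred)) {
    warning(length(deferred), " branch(es) without samples inherit the value",
            " at the head of their downstream branch", call. = FALSE)
    for (pass in seq_len(length(deferred) + 1)) {
      still <- character(0)
      for (b in deferred) {
        dn <- topology$downstream_id[topology$branch_id == b]
        if (!is.na(dn) && !is.na(head_val[dn])) {
          rr <- reaches[reaches$branch_id == b, , drop = FALSE]
          reach_val[rr$reach_id] <- head_val[dn]
          end_val[b] <- head_val[dn]
          head_val[b] <- head_val[dn]
        } else {
          still <- c(still, b)
        }
      }
      deferred <- still
      if (!length(deferred)) break
    }
    if (length(deferred)) {
      stop("no samples reachable for branch(es): ",
           paste(deferred, collapse = ", "), call. = FALSE)
    }
  }
  data.frame(reach_id = names(reach_val), conc = unname(reach_val),
             stringsAsFactors = FALSE)
}

#' Assign each reach to its nearest anchor station
#'
#' Anchors are the temporally resolved measurement points (biweekly manual
#' CH4 stations, daily-mean CO2 sensors). Each reach maps to the anchor with
#' the smallest along-network distance from its midpoint.
#'
#' @param reaches Reach table from [discretize()].
#' @param anchors Data frame `anchor_id`, `branch_id`, `distance_m`.
#' @param topology Data frame `branch_id`, `downstream_id`.
#' @return Data frame `reach_id`, `anchor_id`.
#' @export
assign_anchors <- function(reaches, anchors, topology) {
  meta <- .branch_meta(reaches)
  bl <- stats::setNames(meta$length_m, meta$branch_id)
  pick <- vapply(seq_len(nrow(reaches)), function(i) {
    d <- vapply(seq_len(nrow(anchors)), function(j) {
      network_distance(reaches$branch_id[i], reaches$midpoint_m[i],
                       anchors$branch_id[j], anchors$distance_m[j],
                       topology, bl)
    }, numeric(1))
    anchors$anchor_id[which.min(d)]
  }, character(1))
  data.frame(reach_id = reaches$reach_id, anchor_id = pick,
             stringsAsFactors = FALSE)
}

#' Per-reach concentration ratios relative to anchors
#'
#' For every survey date, each reach's interpolated concentration is divided
#' by the concentration of its assigned anchor on that date; the per-reach
#' ratio is the mean over surveys and its coefficient of variation (sd/mean)
#' quantifies how stable the spatial pattern is, which drives the emission
#' uncertainty bounds (see [uncertainty_pct()]).
#'
#' @param interp Data frame `date`, `reach_id`, `conc` - the output of
#'   [spatial_interpolate()] stacked over survey dates.
#' @param anchor_series Data frame `date`, `anchor_id`, `conc` with anchor
#'   concentrations covering the survey dates.
#' @param assignment Data frame `reach_id`, `anchor_id` from
#'   [assign_anchors()].
#' @return Data frame `reach_id`, `anchor_id`, `ratio`, `cv`, `n_surveys`.
#'   With a single survey the cv is reported as 0 (no repeat information).
#' @export
relative_ratios <- function(interp, anchor_series, assignment) {
  m <- merge(interp, assignment, by = "reach_id")
  m <- merge(m, anchor_series, by = c("date", "anchor_id"),
             suffixes = c("", "_anchor"))
  if (!nrow(m)) stop("no survey dates overlap the anchor series",
                     call. = FALSE)
  if (any(m$conc_anchor <= 0)) {
    stop("anchor concentrations must be positive", call. = FALSE)
  }
  m$r <- m$conc / m$conc_anchor
  sp <- split(m, m$reach_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    mu <- mean(d$r)
    cv <- if (nrow(d) > 1) stats::sd(d$r) / mu else 0
    data.frame(reach_id = d$reach_id[1], anchor_id = d$anchor_id[1],
               ratio = mu, cv = cv, n_surveys = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Reconstruct daily reach concentrations from anchors and ratios
#'
#' Each reach's daily concentration is its spatial ratio times its anchor's
#' gap-filled series: anchor values between sampling dates are linearly
#' interpolated; days before the first or after the last anchor sample carry
#' the nearest value and are flagged `extrapolated`.
#'
#' @param anchor_series Data frame `date`, `anchor_id`, `conc` (sparse or
#'   daily).
#' @param ratios Data frame `reach_id`, `anchor_id`, `ratio` from
#'   [relative_ratios()].
#' @param dates Vector of target dates (class Date).
#' @return Data frame `reach_id`, `date`, `conc`, `extrapolated`.
#' @export
temporal_reconstruct <- function(anchor_series, ratios, dates) {
  dates <- sort(unique(dates))
  filled <- do.call(rbind, lapply(split(anchor_series,
                                        anchor_series$anchor_id),
    function(a) {
      a <- a[order(a$date), , drop = FALSE]
      if (nrow(a) == 1) {
        conc <- rep(a$conc, length(dates))
      } else {
        conc <- stats::approx(as.numeric(a$date), a$conc,
                              xout = as.numeric(dates), rule = 2)$y
      }
      data.frame(anchor_id = a$anchor_id[1], date = dates, conc = conc,
                 extrapolated = dates < min(a$date) | dates > max(a$date),
                 stringsAsFactors = FALSE)
    }))
  m <- merge(ratios[, c("reach_id", "anchor_id", "ratio")], filled,
             by = "anchor_id")
  out <- data.frame(reach_id = m$reach_id, date = m$date,
                    conc = m$ratio * m$conc, extrapolated = m$extrapolated,
                    stringsAsFactors = FALSE)
  out[order(out$reach_id, out$date), , drop = FALSE]
}

#' Spatial-interpolation uncertainty as a percentage
#'
#' The dominating uncertainty of the upscaled emissions comes from assuming
#' the survey-derived spatial ratios hold between surveys. Following the
#' conservative convention used here, the uncertainty attached to network
#' mean emissions is the maximum per-reach ratio CV, expressed in percent.
#'
#' @param cv Vector of per-reach ratio CVs (from [relative_ratios()]).
#' @return Percentage (100 * max CV).
#' @export
uncertainty_pct <- function(cv) {
  if (!length(cv)) stop("no CVs supplied", call. = FALSE)
  100 * max(cv, na.rm = TRUE)
}
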