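#' Soma-referenced bleaching correction of a ROI trace
#'
#' The soma's relative fluorescence loss over time is taken as the
#' bleaching course and subtracted: both traces are expressed relative to
#' their own \eqn{F_0}, the soma's relative change is rescaled to the
#' ROI's \eqn{F_0}, and the corrected change is
#' \deqn{\Delta F_{corr}(t) = F_0^{roi} \left[ \frac{F_{roi}(t)}{F_0^{roi}}
#'   - \frac{F_{soma}(t)}{F_0^{soma}} \right].}
#' This removes exactly any bleaching that scales ROI and soma by the
#' same relative factor, independent of their absolute brightness.
#'
#' @param trace,soma_trace `dcv_roi_trace` objects of equal length.
#' @return Corrected \eqn{\Delta F} sequence in counts (divide by
#'   `trace$F0` for \eqn{\Delta F / F_0}).
#' @export
bleach_correct <- function(trace, soma_trace) {
  if (length(trace$values) != length(soma_trace$values))
    stop("length mismatch between ROI and soma traces")
  (dff(trace) - dff(soma_trace)) * trace$F0
}

#' Activity-dependent dispersion profiles of a synaptic protein
#'
#' For each synaptic and extra-synaptic ROI, extracts the 2x2 trace,
#' applies the soma-referenced bleaching correction, and expresses it as
#' \eqn{\Delta F / F_0}. Returns per-ROI profiles, group mean +/- SEM per
#' frame, and the corrected \eqn{\Delta F / F_0} of every ROI at the
#' report time (default 160 s). Synaptic dispersion shows as a negative
#' synaptic profile with an extra-synaptic gain.
#'
#' @param movie A `dcv_movie`.
#' @param channel Protein channel.
#' @param synaptic_rois,extra_rois data.frames with `y_px`, `x_px`
#'   (0-based ROI centers); either may be empty.
#' @param soma_roi `c(y0, x0, y1, x1)` soma rectangle for the bleach
#'   reference.
#' @param protocol A `dcv_protocol`.
#' @param report_time_s Time at which the summary value is read
#'   (default 160).
#' @param roi_size ROI side in px (default 2).
#' @return List of class `dcv_dispersion`: `profiles` (long data.frame:
#'   `roi`, `class`, `frame`, `time_s`, `dff_corr`), `group` (per class
#'   and frame: `mean`, `sem`, `n`), `at_report` (per ROI value at the
#'   report time), `report_time_s`.
#' @export
dispersion_profiles <- function(movie, channel, synaptic_rois, extra_rois,
                                soma_roi, protocol, report_time_s = 160,
                                roi_size = 2) {
  soma_tr <- extract_region_trace(movie, channel, soma_roi, protocol)
  one_class <- function(rois, label) {
    if (is.null(rois) || nrow(rois) == 0) {
      warning("empty ROI set for class ", label)
      return(NULL)
    }
    out <- vector("list", nrow(rois))
    for (i in seq_len(nrow(rois))) {
      tr <- extract_trace(movie, channel, c(rois$y_px[i], rois$x_px[i]),
                          roi_size = roi_size, protocol = protocol)
      corr <- bleach_correct(tr, soma_tr) / tr$F0
      out[[i]] <- data.frame(roi = paste0(label, "_", i), class = label,
                             frame = seq_along(corr),
                             time_s = frame_to_time(protocol, seq_along(corr)),
                             dff_corr = corr)
    }
    do.call(rbind, out)
  }
  profiles <- rbind(one_class(synaptic_rois, "synaptic"),
                    one_class(extra_rois, "extra-synaptic"))
  if (is.null(profiles)) stop("no ROIs supplied")
  agg_m <- stats::aggregate(dff_corr ~ class + frame, profiles, mean)
  agg_s <- stats::aggregate(dff_corr ~ class + frame, profiles,
                            function(x) stats::sd(x) / sqrt(length(x)))
  agg_n <- stats::aggregate(dff_corr ~ class + frame, profiles, length)
  group <- data.frame(class = agg_m$class, frame = agg_m$frame,
                      time_s = frame_to_time(protocol, agg_m$frame),
                      mean = agg_m$dff_corr, sem = agg_s$dff_corr,
                      n = agg_n$dff_corr)
  rep_frame <- min(time_to_frame(protocol, report_time_s), protocol$n_frames)
  at_report <- profiles[profiles$frame == rep_frame,
                        c("roi", "class", "dff_corr")]
  structure(list(profiles = profiles, group = group, at_report = at_report,
                 report_time_s = report_time_s, report_frame = rep_frame),
            class = "dcv_dispersion")
}
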