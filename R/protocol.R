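#' Inversion-recovery mapping protocol
#'
#' Describes the single-shot TSE inversion-recovery T1 protocol: a set of
#' inversion delays plus one image acquired without an inversion pulse, the
#' repetition time, the shot duration and the minimum longitudinal recovery
#' enforced between acquisitions.
#'
#' The no-inversion image is represented by `ti = Inf` in the signal model
#' (the fully recovered signal), but uses `ti = 0` when computing recovery
#' delays since no inversion time elapses before the readout.
#'
#' @param ti_s Inversion delays in seconds (finite, strictly increasing).
#' @param tr_s Repetition time in seconds.
#' @param t_shot_s TSE shot duration in seconds.
#' @param min_recovery_s Minimum recovery time enforced between acquisitions.
#' @param refocus_deg Refocusing flip angle of the readout train, degrees.
#' @param include_noinv Include the no-inversion image (flagged as `Inf`).
#' @return An object of class `ir_protocol`.
#' @export
ir_protocol <- function(ti_s = c(0.5, 1.0, 1.5, 2.0, 3.0, 4.0, 5.0),
                        tr_s = 10, t_shot_s = 0.37, min_recovery_s = 20,
                        refocus_deg = 120, include_noinv = TRUE) {
  stopifnot(all(is.finite(ti_s)), all(ti_s > 0), !is.unsorted(ti_s, strictly = TRUE),
            tr_s > 0, t_shot_s > 0, min_recovery_s > 0)
  if (any(ti_s >= tr_s)) stop("inversion delays must be shorter than TR")
  structure(list(ti_s = ti_s, tr_s = tr_s, t_shot_s = t_shot_s,
                 min_recovery_s = min_recovery_s, refocus_deg = refocus_deg,
                 include_noinv = include_noinv),
            class = "ir_protocol")
}

#' Full inversion-time list of an IR protocol
#'
#' @param proto An `ir_protocol`.
#' @return Inversion times in seconds, with `Inf` marking the no-inversion
#'   image if the protocol includes one.
#' @export
ir_ti_full <- function(proto) {
  stopifnot(inherits(proto, "ir_protocol"))
  if (proto$include_noinv) c(proto$ti_s, Inf) else proto$ti_s
}

#' Recovery delay needed after an inversion-recovery acquisition
#'
#' The added delay Tdelay is the smallest non-negative value such that
#' `tr - ti + t_shot + Tdelay >= min_recovery`, ensuring consistent
#' longitudinal recovery before the next inversion. Pass `ti = 0` for the
#' no-inversion image.
#'
#' @param ti Inversion delay in seconds, `0 <= ti < tr`.
#' @param proto An `ir_protocol`.
#' @return Delay in seconds.
#' @export
recovery_delay <- function(ti, proto) {
  stopifnot(inherits(proto, "ir_protocol"), is.numeric(ti), all(is.finite(ti)), all(ti >= 0))
  if (any(ti >= proto$tr_s)) stop("invalid protocol: ti must be less than TR")
  pmax(0, proto$min_recovery_s - (proto$tr_s - ti + proto$t_shot_s))
}

#' Multi-echo TSE mapping protocol
#'
#' Describes the multi-shot 2D TSE used for T2 mapping: echo train length,
#' the nominal echo times of the k-space-centre echoes and their positions in
#' the train, the refocusing flip angle and slice thickness.
#'
#' The echo spacing used for signal timing is derived from the last
#' k-space-centre echo (`te_centers_ms[length(te_centers_ms)] / etl`) so that
#' the decay model is anchored to the stated echo times; the vendor-quoted
#' nominal spacing is retained as metadata only.
#'
#' @param etl Echo train length.
#' @param te_centers_ms Nominal echo times of the k-space centres, ms.
#' @param echo_indices 1-based echo numbers of the k-space centres.
#' @param refocus_deg Nominal refocusing flip angle, degrees.
#' @param tr_s Repetition time, seconds.
#' @param slice_thickness_mm Slice thickness, mm.
#' @param esp_nominal_ms Vendor-quoted echo spacing (metadata), ms.
#' @return An object of class `tse_protocol` with derived `echo_spacing_ms`.
#' @export
tse_protocol <- function(etl = 24, te_centers_ms = c(59, 154, 283),
                         echo_indices = c(5, 13, 24), refocus_deg = 180,
                         tr_s = 5, slice_thickness_mm = 1.6,
                         esp_nominal_ms = 11.2) {
  stopifnot(etl >= 1, length(te_centers_ms) == length(echo_indices),
            all(echo_indices >= 1), all(echo_indices <= etl),
            !is.unsorted(echo_indices, strictly = TRUE),
            all(te_centers_ms > 0), tr_s > 0, slice_thickness_mm > 0)
  structure(list(etl = as.integer(etl), te_centers_ms = te_centers_ms,
                 echo_indices = as.integer(echo_indices),
                 refocus_deg = refocus_deg, tr_s = tr_s,
                 slice_thickness_mm = slice_thickness_mm,
                 esp_nominal_ms = esp_nominal_ms,
                 echo_spacing_ms = te_centers_ms[length(te_centers_ms)] / etl),
            class = "tse_protocol")
}

#' Echo-centre times of a TSE protocol
#'
#' @param proto A `tse_protocol`.
#' @return Echo times in ms for echoes `1:etl`.
#' @export
tse_echo_times_ms <- function(proto) {
  stopifnot(inherits(proto, "tse_protocol"))
  seq_len(proto$etl) * proto$echo_spacing_ms
}

#' Serialize a protocol to JSON
#'
#' Times are stored in SI seconds except fields explicitly suffixed `_ms`.
#'
#' @param proto An `ir_protocol` or `tse_protocol`.
#' @return A JSON string.
#' @export
protocol_to_json <- function(proto) {
  stopifnot(inherits(proto, c("ir_protocol", "tse_protocol")))
  jsonlite::toJSON(c(list(.class = class(proto)[1]), unclass(proto)),
                   auto_unbox = TRUE, digits = NA)
}

#' Deserialize a protocol from JSON
#'
#' @param json A JSON string produced by [protocol_to_json()].
#' @return The protocol object.
#' @export
protocol_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  cls <- x$.class
  x$.class <- NULL
  if (identical(cls, "ir_protocol")) {
    do.call(ir_protocol, x[c("ti_s", "tr_s", "t_shot_s", "min_recovery_s",
                             "refocus_deg", "include_noinv")])
  } else if (identical(cls, "tse_protocol")) {
    do.call(tse_protocol, x[c("etl", "te_centers_ms", "echo_indices",
                              "refocus_deg", "tr_s", "slice_thickness_mm",
                              "esp_nominal_ms")])
  } else stop("unknown protocol class in JSON: ", cls)
}
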