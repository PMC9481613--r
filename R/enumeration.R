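#' Enumerate fixed-length duplication windows over a promoter range
#'
#' One window per upstream-end magnitude `X` in `x_from..x_to`, each spanning
#' `c.-X` to `c.-(X-k+1)`. Ordered by `X` descending (most upstream first).
#'
#' @param k window length in bp (>= 1).
#' @param x_from,x_to inclusive range of upstream-end magnitudes `|X|`
#'   (`x_from >= x_to`).
#' @return data.frame with columns `c_up`, `c_down`, `label`.
#' @examples
#' nrow(enumerate_windows(22, 121, 88)) # 34
#' @export
enumerate_windows <- function(k, x_from, x_to) {
  stopifnot(k >= 1L, x_from >= x_to, x_to >= k)
  xs <- seq(as.integer(x_from), as.integer(x_to), by = -1L)
  data.frame(
    c_up = -xs,
    c_down = -(xs - as.integer(k) + 1L),
    label = paste0("c.", -xs, "_", -(xs - as.integer(k) + 1L)),
    stringsAsFactors = FALSE
  )
}

#' Annotated report over all k-bp duplication windows
#'
#' For every window: the variant sequence it produces, its motif content,
#' its byte-identity equivalence class, whether it is the canonical
#' (left-aligned) class member, and its predicted activity class. Windows
#' producing identical variant sequences necessarily share all annotation.
#'
#' The default range (`k = 22`, `X` from 121 down to 88) is the full panel of
#' 22-bp windows spanning the native ETS cassette and beyond; it requires
#' reference coverage down to c.-67, which the bundled reconstructed promoter
#' window provides.
#'
#' @param ref a [promoter_reference()] covering every window.
#' @param map a [coordinate_map()].
#' @param k,x_from,x_to see [enumerate_windows()].
#' @param cfg a [phase_config()].
#' @param registry a [motif_registry()].
#' @return data.frame with one row per window; the class partition is
#'   attached as `attr(, "classes")` (see [equivalence_classes()]).
#' @export
window_panel_report <- function(ref, map, k = 22L, x_from = 121L, x_to = 88L,
                         cfg = phase_config(), registry = motif_registry()) {
  windows <- enumerate_windows(k, x_from, x_to)
  lo <- c_to_genomic(map, windows$c_down)
  hi <- c_to_genomic(map, windows$c_up)
  uncovered <- lo < ref$start_genomic | hi > ref_end(ref)
  if (any(uncovered)) {
    stop(
      "reference does not cover window(s): ",
      paste(windows$label[uncovered], collapse = ", ")
    )
  }
  classes <- equivalence_classes(ref, map, windows)
  class_of <- stats::setNames(
    rep(seq_along(classes), vapply(classes, function(cl) nrow(cl$members), integer(1))),
    unlist(lapply(classes, function(cl) paste0(cl$members$c_up, "_", cl$members$c_down)))
  )
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    call <- duplication_from_region(ref, map, windows$c_up[i], windows$c_down[i])
    variant <- apply_insertion(ref, as_insertion(call))
    sites <- assign_origin(ref, variant, call, cfg)
    act <- classify_activity(call, sites, cfg, registry = registry)
    contains <- template_contains_sites(call, registry)
    key <- paste0(windows$c_up[i], "_", windows$c_down[i])
    cls <- class_of[[key]]
    canonical <- all(abs(classes[[cls]]$canonical) == abs(c(windows$c_up[i], windows$c_down[i])))
    data.frame(
      label = windows$label[i],
      c_up = windows$c_up[i], c_down = windows$c_down[i],
      template_start = lo[i], template_end = hi[i],
      n_sites = nrow(sites),
      n_de_novo = sum(sites$origin != "native"),
      contains_ets200 = unname(contains["ETS 200"]),
      contains_ets195 = unname(contains["ETS 195"]),
      class_id = cls,
      canonical = canonical,
      predicted_activity = act$klass,
      variant_seq_hash = classes[[cls]]$variant_seq_hash,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "classes") <- classes
  out
}

#' Summary of a window-enumeration report
#'
#' @param report output of [window_panel_report()].
#' @return list with `windows` (total count), `unique` (distinct variant
#'   sequences) and `classes` (list of member label vectors, canonical first).
#' @export
window_panel_summary <- function(report) {
  classes <- attr(report, "classes")
  list(
    windows = nrow(report),
    unique = length(classes),
    classes = lapply(classes, function(cl) {
      paste0("c.", cl$members$c_up, "_", cl$members$c_down)
    })
  )
}

#' Write a window-enumeration report as TSV plus a JSON summary
#'
#' @param report output of [window_panel_report()].
#' @param tsv,json output paths (`NULL` to skip either).
#' @return the summary list, invisibly.
#' @export
write_window_panel_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(report, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- window_panel_summary(report)
  if (!is.null(json)) {
    jsonlite::write_json(summary, json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(summary)
}
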