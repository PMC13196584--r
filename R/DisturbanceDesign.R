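#' Construct a disturbance-frequency design
#'
#' @param levels integer vector of level ids (default `0:(L-1)`).
#' @param frequencies numeric, disturbance events per day per level,
#'   non-decreasing.
#' @param regimes character, regime class per level
#'   (`"undisturbed"`/`"intermediate"`/`"press"`).
#' @param replicates integer, replicates per level (recycled).
#' @param day integer sampling-day label.
#'
#' @return A [DisturbanceDesign-class] object.
#' @examples
#' disturbanceDesign(frequencies = c(0, 1/2, 1),
#'                   regimes = c("undisturbed", "intermediate", "press"),
#'                   replicates = 3)
#' @export
disturbanceDesign <- function(frequencies,
                              regimes,
                              replicates = 5L,
                              levels = seq_along(frequencies) - 1L,
                              day = 42L) {
  L <- length(frequencies)
  new("DisturbanceDesign",
      levels = as.integer(levels),
      frequencies = as.numeric(frequencies),
      regimes = as.character(regimes),
      replicates = as.integer(rep_len(replicates, L)),
      day = as.integer(day))
}

#' The default six-level design
#'
#' Six disturbance levels at frequencies 0, 1/8, 1/6, 1/4, 1/2 and 1
#' events/day with five replicates each, sampled at day 42. Level 0 is the
#' undisturbed regime, levels 1-4 the intermediate (pulse) regime, and
#' level 5 the press regime.
#'
#' @return A [DisturbanceDesign-class].
#' @examples
#' defaultDesign()
#' @export
defaultDesign <- function() {
  disturbanceDesign(
    frequencies = c(0, 1/8, 1/6, 1/4, 1/2, 1),
    regimes = c("undisturbed", rep("intermediate", 4L), "press"),
    replicates = 5L)
}

#' @describeIn disturbanceDesign Level ids.
#' @param object,x a `DisturbanceDesign`.
#' @export
setGeneric("designLevels", function(object) standardGeneric("designLevels"))

#' @rdname disturbanceDesign
#' @export
setMethod("designLevels", "DisturbanceDesign", function(object) object@levels)

#' @rdname disturbanceDesign
#' @export
setGeneric("designRegimes", function(object) standardGeneric("designRegimes"))

#' @rdname disturbanceDesign
#' @export
setMethod("designRegimes", "DisturbanceDesign",
          function(object) setNames(object@regimes, object@levels))

#' @rdname disturbanceDesign
#' @export
setGeneric("designReplicates",
           function(object) standardGeneric("designReplicates"))

#' @rdname disturbanceDesign
#' @export
setMethod("designReplicates", "DisturbanceDesign",
          function(object) setNames(object@replicates, object@levels))

#' Expand a design into per-sample metadata
#'
#' One row per sample with ids of the form `L<level>R<replicate>`.
#'
#' @param design a [DisturbanceDesign-class].
#' @return `data.frame` with columns `sample_id`, `level`, `regime`,
#'   `replicate`, `day`.
#' @examples
#' head(designSamples(defaultDesign()))
#' @export
designSamples <- function(design) {
  stopifnot(is(design, "DisturbanceDesign"))
  lv <- rep(design@levels, design@replicates)
  rg <- rep(design@regimes, design@replicates)
  rp <- unlist(lapply(design@replicates, seq_len), use.names = FALSE)
  data.frame(sample_id = paste0("L", lv, "R", rp),
             level = lv, regime = rg, replicate = rp,
             day = design@day, stringsAsFactors = FALSE)
}

#' @rdname disturbanceDesign
#' @export
setMethod("show", "DisturbanceDesign", function(object) {
  cat("DisturbanceDesign with", length(object@levels), "levels (day",
      object@day, ")\n")
  print(data.frame(level = object@levels, frequency = object@frequencies,
                   regime = object@regimes, replicates = object@replicates),
        row.names = FALSE)
  invisible(NULL)
})

## regime ordering used for tie-breaks throughout
regimeOrder <- function() c("undisturbed", "intermediate", "press")
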