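#' Construct a cohort specification
#'
#' Convenience constructor for [CohortSpec-class] with the default study
#' layout: 17 healthy controls (HC) receiving the model's full condition
#' effect and 5 MCS + 6 UWS patients with the effect silenced
#' (`groupEffectScale` 0), i.e. a cohort in which only the HC group responds
#' to the acquaintance videos.
#'
#' @param nPerGroup named counts for HC/MCS/UWS.
#' @param groupEffectScale named multipliers on the model's condition deltas.
#' @param model shared [HeartPeriodModel-class].
#' @param seed master seed.
#' @param withECG synthesize waveforms per subject (slower; needed only when
#'   exercising the waveform chain).
#' @param fs,noise ECG synthesis settings (see [synthesizeECG()]).
#' @param ectopicFraction proportion of beats displaced as ectopics.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nPerGroup = c(HC = 17L, MCS = 5L, UWS = 6L),
                       groupEffectScale = c(HC = 1, MCS = 0, UWS = 0),
                       model = new("HeartPeriodModel"),
                       seed = 1L, withECG = FALSE, fs = 256,
                       noise = list(wanderAmp = 0.2, wanderFreq = 0.25,
                                    mainsAmp = 0.05, whiteSd = 0.05),
                       ectopicFraction = 0) {
  new("CohortSpec",
      nPerGroup = vapply(nPerGroup, as.integer, integer(1)),
      groupEffectScale = groupEffectScale, model = model,
      seed = as.integer(seed), withECG = withECG, fs = fs, noise = noise,
      ectopicFraction = ectopicFraction)
}

#' Generate a seeded synthetic cohort
#'
#' One subject record per requested participant. Per-subject seeds are drawn
#' once from the master seed, so the whole cohort is a pure function of the
#' spec. Each subject gets an own randomized protocol, a beat series from the
#' shared heart-period model with the group's effect multiplier applied to
#' the condition deltas, optionally injected ectopics, and (when `withECG`)
#' a synthesized waveform.
#'
#' @param spec a [CohortSpec-class].
#' @return List of subject records: `list(id, group, seed, protocol, beats,
#'   ecg)` (`ecg` is `NULL` at beat level).
#' @export
#' @examples
#' cohort <- generateCohort(cohortSpec(nPerGroup = c(HC = 2, MCS = 1, UWS = 1)))
#' vapply(cohort, `[[`, character(1), "group")
generateCohort <- function(spec) {
  validObject(spec)
  groups <- rep(GROUPS, times = spec@nPerGroup[GROUPS])
  nTot <- length(groups)
  if (nTot == 0L) return(list())
  subjSeeds <- withSeed(spec@seed, sample.int(2147483646L, nTot * 3L))
  lapply(seq_len(nTot), function(i) {
    g <- groups[i]
    scale <- spec@groupEffectScale[[g]]
    model <- spec@model
    model@delta <- model@delta * scale
    protocol <- generateProtocol(seed = subjSeeds[3L * i - 2L])
    beats <- generateBeats(protocol, model, seed = subjSeeds[3L * i - 1L])
    if (spec@ectopicFraction > 0)
      beats <- injectEctopics(beats, spec@ectopicFraction,
                              seed = subjSeeds[3L * i])
    ecg <- if (spec@withECG)
      synthesizeECG(beats, fs = spec@fs, noise = spec@noise,
                    seed = subjSeeds[3L * i])
    list(id = sprintf("S%03d", i), group = g, seed = subjSeeds[3L * i - 2L],
         protocol = protocol, beats = beats, ecg = ecg)
  })
}
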