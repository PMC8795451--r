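# YAML run configuration: profile files override the built-in defaults.

#' Read a run-configuration YAML
#'
#' A configuration file may override any field of the detector, FPR or
#' training configurations. The packaged full profile
#' (`system.file("extdata", "luna16-full.yaml", package = "nodulemsa")`)
#' records the paper-scale settings (96^3 patches, 100 epochs, tenfold
#' cross-validation on LUNA16), which require GPU-scale compute and the
#' external dataset; the built-in desk profile is the default everywhere
#' else.
#'
#' @param path YAML file, or NULL for the desk profile.
#' @return list with `detector` ([detector_config()]), `fpr`
#'   ([fpr_config()]) and `train` ([train_config()]).
#' @export
read_config <- function(path = NULL) {
  base <- list(detector = unclass(desk_detector_config()),
               fpr = unclass(desk_fpr_config()),
               train = unclass(train_config()))
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    for (part in intersect(names(y), names(base)))
      base[[part]] <- utils::modifyList(base[[part]], y[[part]])
  }
  det <- base$detector
  fp <- base$fpr
  list(detector = detector_config(det$input_size, unlist(det$widths),
                                  det$blocks_per_stage, det$decoder_blocks,
                                  det$decoder_channels, unlist(det$anchors),
                                  det$k_att),
       fpr = fpr_config(fp$input_size, unlist(fp$widths), fp$stem_width,
                        fp$dropout, fp$k_att),
       train = structure(base$train, class = "train_config"))
}
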