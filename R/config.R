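#' Config-driven single-subject refinement
#'
#' A YAML run configuration names the input files, the candidate
#' segmentations and the tunable parameters, and [run_refine_config()]
#' executes the full subject pipeline from it. Reruns on identical inputs are
#' deterministic.
#'
#' Expected structure (YAML):
#' \preformatted{
#' subject: case001
#' paths:
#'   pre: t1_pre.nii.gz
#'   post: t1_post.nii.gz
#'   csf_reference: ventricle.nii.gz    # or: labels + label_id
#'   # labels: whole_brain_seg.nii.gz
#'   # label_id: 43
#' candidates:
#'   - {name: algA, side: right, path: algA_right.nii.gz, type: binary}
#'   - {name: algB, side: right, path: algB_right_prob.nii.gz, type: probability}
#' parameters:
#'   k_gm: 1
#'   k_csf: 1
#'   k_enh: 1
#'   thresholds: [0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1]
#' output_dir: out/
#' }
#'
#' @param config list as parsed from YAML (see [read_run_config()]).
#' @param out_dir output directory; defaults to `config$output_dir`.
#' @return the [run_refine_subject()] result, invisibly.
#' @export
run_refine_config <- function(config, out_dir = config$output_dir) {
  base <- config$base_dir %||% "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  pre <- read_intensity_volume(resolve(config$paths$pre))
  post <- read_intensity_volume(resolve(config$paths$post))
  if (!is.null(config$paths$csf_reference)) {
    csf_ref <- read_binary_mask(resolve(config$paths$csf_reference),
                                label = "csf_reference")
  } else if (!is.null(config$paths$labels)) {
    labels <- read_intensity_volume(resolve(config$paths$labels))
    csf_ref <- extract_label_mask(labels, config$paths$label_id %||% 43)
  } else stop("config needs paths$csf_reference or paths$labels", call. = FALSE)
  if (is.null(config$candidates) || length(config$candidates) < 1L)
    stop("config lists no candidate segmentations", call. = FALSE)
  candidates <- list()
  for (entry in config$candidates) {
    side <- entry$side %||% "right"
    type <- entry$type %||% "binary"
    candidates[[entry$name]][[side]] <-
      if (identical(type, "probability"))
        list(prob = read_probability_map(resolve(entry$path)))
      else list(mask = read_binary_mask(resolve(entry$path), label = entry$name))
  }
  p <- config$parameters %||% list()
  invisible(run_refine_subject(
    pre, post, candidates, csf_ref,
    subject = config$subject %||% "subject",
    thresholds = unlist(p$thresholds) %||% seq(0, 1, 0.1),
    out_dir = out_dir,
    k_gm = p$k_gm %||% 1, k_csf = p$k_csf %||% 1, k_enh = p$k_enh %||% 1))
}

#' Read a YAML run configuration
#' @param path path to the YAML file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  cfg
}
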