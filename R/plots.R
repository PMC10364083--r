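#' Plot a per-residue exposure profile
#'
#' Bar plot of relative solvent exposure with the exposed/buried threshold
#' bands used for cysteine classification; cysteines are highlighted.
#'
#' @param profile exposure profile tibble.
#' @param exposed_threshold,buried_threshold percentages drawn as dashed
#'   guides.
#' @return A ggplot object.
#' @export
plot_exposure_profile <- function(profile, exposed_threshold = 20,
                                  buried_threshold = 7) {
  profile <- dplyr::mutate(profile, is_cys = .data$residue_name == "CYS")
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$residue_seq, y = .data$exposure_pct,
                               fill = .data$is_cys)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::geom_hline(yintercept = c(buried_threshold, exposed_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "#D55E00"),
                               labels = c("other", "cysteine"),
                               name = NULL) +
    ggplot2::labs(x = "residue", y = "exposure (% of Gly-X-Gly maximum)") +
    ggplot2::theme_minimal()
}

#' Plot screened poses
#'
#' Minimum inter-monomer S-S distance per pose, coloured by verdict, with
#' the selection and rejection cutoffs drawn as guides.
#'
#' @param poses tibble from [screen_pose()] / [rank_poses()].
#' @param select_cutoff,reject_cutoff Angstrom guides.
#' @return A ggplot object.
#' @export
plot_screen <- function(poses, select_cutoff = 6, reject_cutoff = 10) {
  poses <- dplyr::mutate(poses, pose = factor(dplyr::row_number()))
  ggplot2::ggplot(poses,
                  ggplot2::aes(x = .data$pose, y = .data$min_ss,
                               colour = .data$verdict)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = c(select_cutoff, reject_cutoff),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(candidate = "#009E73",
                                            marginal = "#E69F00",
                                            rejected = "#D55E00")) +
    ggplot2::labs(x = "pose", y = "min inter-monomer S-S distance (A)") +
    ggplot2::theme_minimal()
}

#' @rdname build_interface_panel
#' @param object an `interface_panel`.
#' @importFrom ggplot2 autoplot
#' @method autoplot interface_panel
#' @export
autoplot.interface_panel <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_frame, -dplyr::all_of("model"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL,
                  title = "Interface metrics per frame") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
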