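#' Generate the three-class 3-D toy dataset
#'
#' Draws three well-separated uniform point clouds in three dimensions, the
#' standard small benchmark for label propagation through a shared basis:
#' class c samples are `means[c, ] + noise_scales[c] * x` with
#' `x ~ U(0,1)^3` i.i.d. The default means are (1, 0.8, 0.8), (0.8, 0.8, 0.8)
#' and (0.8, 1, 0.7) with noise scales 0.1, 0.1 and 0.15, ten samples per
#' class of which the first three are labeled — 30 samples, 9 labeled,
#' 21 unlabeled. All values are strictly positive, so the result is a valid
#' input for [semipnmf()].
#'
#' @param n_per_class Samples per class (default 10).
#' @param n_labeled_per_class Labeled samples per class, taken as the first
#'   of each class in generation order (default 3; samples are i.i.d. so the
#'   choice is exchangeable).
#' @param means 3 x 3 matrix of class means (rows = classes).
#' @param noise_scales Length-3 positive noise scales.
#' @param seed Integer seed; the same seed reproduces the dataset bit for bit.
#' @return A tibble with one row per sample: `sample_id`, `true_class`
#'   (factor, the generating class), `class` (character, `NA` for unlabeled
#'   samples — pass as `labels` to [semipnmf()]), and gene columns
#'   `g1`, `g2`, `g3`.
#' @examples
#' toy <- generate_toy(seed = 7)
#' dplyr::count(toy, true_class, labeled = !is.na(class))
#' @export
generate_toy <- function(n_per_class = 10, n_labeled_per_class = 3,
                         means = rbind(c(1, 0.8, 0.8),
                                       c(0.8, 0.8, 0.8),
                                       c(0.8, 1, 0.7)),
                         noise_scales = c(0.1, 0.1, 0.15),
                         seed = 1L) {
  means <- as.matrix(means)
  stopifnot(nrow(means) == length(noise_scales), ncol(means) == 3,
            n_per_class >= 1, n_labeled_per_class >= 0,
            n_labeled_per_class <= n_per_class, all(noise_scales > 0))
  r <- nrow(means)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  class_names <- paste0("C", seq_len(r))
  blocks <- lapply(seq_len(r), function(c) {
    noise <- matrix(runif(n_per_class * 3), n_per_class, 3)
    sweep(noise_scales[c] * noise, 2, means[c, ], "+")
  })
  V <- do.call(rbind, blocks)
  colnames(V) <- c("g1", "g2", "g3")
  truth <- rep(class_names, each = n_per_class)
  labeled <- rep(seq_len(n_per_class) <= n_labeled_per_class, times = r)
  tibble(
    sample_id = sprintf("s%02d", seq_len(r * n_per_class)),
    true_class = factor(truth, levels = class_names),
    class = ifelse(labeled, truth, NA_character_)
  ) |>
    dplyr::bind_cols(as_tibble(V))
}
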