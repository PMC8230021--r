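#' Specification for a synthetic decision table
#'
#' Parameters of the synthetic-table generator, which emulates the regime
#' the selector targets: a few informative dimensions buried among
#' class-independent noise, at desk scale. Relevant features carry
#' class-conditional Gaussian signal; redundant features are jittered affine
#' copies of relevant ones; noise features are class-independent uniform.
#'
#' @param n_samples Number of samples (balanced across classes up to
#'   rounding).
#' @param n_classes Number of decision classes.
#' @param n_relevant Informative features (`>= 1`).
#' @param n_redundant Affine copies of randomly chosen relevant features.
#' @param n_noise Class-independent uniform features.
#' @param class_separation Distance between consecutive per-class feature
#'   means, in units of the within-class spread `noise_sd`.
#' @param noise_sd Within-class standard deviation of the relevant features.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return An object of class `synthetic_spec` (validated list).
#' @export
synthetic_spec <- function(n_samples = 80, n_classes = 2, n_relevant = 2,
                           n_redundant = 0, n_noise = 20,
                           class_separation = 5, noise_sd = 0.05, seed = 1) {
  stopifnot(n_samples >= n_classes, n_classes >= 1, n_relevant >= 1,
            n_redundant >= 0, n_noise >= 0, class_separation > 0,
            noise_sd >= 0)
  structure(
    list(n_samples = as.integer(n_samples), n_classes = as.integer(n_classes),
         n_relevant = as.integer(n_relevant),
         n_redundant = as.integer(n_redundant), n_noise = as.integer(n_noise),
         class_separation = class_separation, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic decision table with known relevant features
#'
#' Draws a table per the [synthetic_spec()]: labels are balanced across
#' classes; each relevant feature has class-conditional Gaussian values with
#' per-class means spaced `class_separation * noise_sd` apart and standard
#' deviation `noise_sd`; redundant features are affine transforms of random
#' relevant features plus small jitter; noise features are uniform on
#' `[0, 1]` independent of the class. All columns are then min-max
#' normalized. Feature order is relevant, redundant, noise, and the ground
#' truth partition is returned alongside the table.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (a normalized [decision_table]) and
#'   `ground_truth`: integer index vectors `relevant`, `redundant`, `noise`.
#' @examples
#' g <- generate_table(synthetic_spec(n_samples = 30, n_noise = 5, seed = 7))
#' g$ground_truth$relevant
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  K <- spec$n_classes
  labels <- rep_len(paste0("c", seq_len(K)), n)
  n_feat <- spec$n_relevant + spec$n_redundant + spec$n_noise
  with_seed(spec$seed, {
    cls <- match(labels, paste0("c", seq_len(K)))
    rel <- matrix(0, n, spec$n_relevant)
    for (f in seq_len(spec$n_relevant)) {
      # random class-to-position assignment so features are not collinear
      pos <- sample(seq_len(K))
      mu <- (pos[cls] - 1) * spec$class_separation * spec$noise_sd
      rel[, f] <- stats::rnorm(n, mean = mu, sd = spec$noise_sd)
    }
    red <- matrix(0, n, spec$n_redundant)
    if (spec$n_redundant > 0L) {
      for (f in seq_len(spec$n_redundant)) {
        src <- sample(spec$n_relevant, 1L)
        a <- stats::runif(1, 0.5, 2)
        b <- stats::runif(1, -0.5, 0.5)
        red[, f] <- a * rel[, src] + b +
          stats::rnorm(n, sd = 0.02 * spec$noise_sd)
      }
    }
    noise <- matrix(stats::runif(n * spec$n_noise), n, spec$n_noise)
    values <- cbind(rel, red, noise)
  })
  colnames(values) <- c(
    if (spec$n_relevant) paste0("rel", seq_len(spec$n_relevant)),
    if (spec$n_redundant) paste0("red", seq_len(spec$n_redundant)),
    if (spec$n_noise) paste0("noise", seq_len(spec$n_noise))
  )
  table <- normalize_min_max(decision_table(values, labels))
  list(
    table = table,
    ground_truth = list(
      relevant = seq_len(spec$n_relevant),
      redundant = spec$n_relevant + seq_len(spec$n_redundant),
      noise = spec$n_relevant + spec$n_redundant + seq_len(spec$n_noise)
    )
  )
}
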