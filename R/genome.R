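#' @importFrom jsonlite read_json write_json
NULL

# Canonical flat layout of the 22 evolvable scalars. Order matters: it is the
# coordinate system of the evolution strategy and of genome JSON files.
.genome_fields <- c(
  "tau_u", "tau_v", "i_ext", "dur_pre", "dur_post", "w_plus",
  "u_gain", "u_offset", "u_threshold",
  "v_gain", "v_offset", "v_threshold",
  "phi_v_alpha", "phi_v_slope", "phi_v_offset", "phi_v_center", "phi_v_width",
  "phi_eta_alpha", "phi_eta_slope", "phi_eta_offset", "phi_eta_center",
  "phi_eta_width"
)

#' Construct an agent genome
#'
#' The agent is governed by 22 scalar hyperparameters: membrane time
#' constants and external input of the two rate populations, the two phase
#' durations of a selection round, the maximum synaptic weight, a
#' thresholded-sigmoid response per population, and two Gaussian-sigmoid
#' filters (the option-value function applied to the plastic weights, and
#' the weight-dependent learning-rate function).
#'
#' @param tau_u,tau_v membrane time constants (ms, > 0) of populations U and V.
#' @param i_ext constant external input delivered to population U during the
#'   first phase of each round.
#' @param dur_pre,dur_post durations (ms) of the input-driven and autonomous
#'   phases of a round; both constrained to \[400, 3000\].
#' @param w_plus maximum synaptic weight (> 0); rewarded updates pull the
#'   chosen arm's weight toward it.
#' @param resp_u,resp_v [response_params()] of populations U and V.
#' @param phi_v [gaussian_sigmoid_params()] of the option-value function
#'   filtering the plastic weights on the U-to-V pathway.
#' @param phi_eta [gaussian_sigmoid_params()] of the learning-rate function;
#'   its output is clipped to \[0, 1\] when used as a learning rate.
#' @return an object of class `nsa_genome`.
#' @seealso [genome_to_vector()], [read_genome()], [default_genome()]
#' @export
nsa_genome <- function(tau_u, tau_v, i_ext, dur_pre, dur_post, w_plus,
                       resp_u, resp_v, phi_v, phi_eta) {
  stopifnot(inherits(resp_u, "response_params"),
            inherits(resp_v, "response_params"),
            inherits(phi_v, "gaussian_sigmoid_params"),
            inherits(phi_eta, "gaussian_sigmoid_params"))
  if (tau_u <= 0 || tau_v <= 0) stop("time constants must be > 0", call. = FALSE)
  if (w_plus <= 0) stop("`w_plus` must be > 0", call. = FALSE)
  if (dur_pre < 400 || dur_pre > 3000 || dur_post < 400 || dur_post > 3000) {
    stop("phase durations must lie in [400, 3000] ms", call. = FALSE)
  }
  structure(list(tau_u = tau_u, tau_v = tau_v, i_ext = i_ext,
                 dur_pre = dur_pre, dur_post = dur_post, w_plus = w_plus,
                 resp_u = resp_u, resp_v = resp_v,
                 phi_v = phi_v, phi_eta = phi_eta),
            class = "nsa_genome")
}

#' @export
print.nsa_genome <- function(x, ...) {
  cat("<nsa_genome> 22 parameters\n")
  v <- genome_to_vector(x)
  print(round(v, 4))
  invisible(x)
}

#' Flatten a genome to its canonical 22-vector
#'
#' @param genome an [nsa_genome()] object.
#' @return named numeric vector of length 22 in the canonical parameter
#'   order used by the evolution strategy and by genome JSON files.
#' @export
genome_to_vector <- function(genome) {
  stopifnot(inherits(genome, "nsa_genome"))
  c(tau_u = genome$tau_u, tau_v = genome$tau_v, i_ext = genome$i_ext,
    dur_pre = genome$dur_pre, dur_post = genome$dur_post,
    w_plus = genome$w_plus,
    u_gain = genome$resp_u$gain, u_offset = genome$resp_u$offset,
    u_threshold = genome$resp_u$threshold,
    v_gain = genome$resp_v$gain, v_offset = genome$resp_v$offset,
    v_threshold = genome$resp_v$threshold,
    phi_v_alpha = genome$phi_v$alpha, phi_v_slope = genome$phi_v$slope,
    phi_v_offset = genome$phi_v$offset, phi_v_center = genome$phi_v$center,
    phi_v_width = genome$phi_v$width,
    phi_eta_alpha = genome$phi_eta$alpha, phi_eta_slope = genome$phi_eta$slope,
    phi_eta_offset = genome$phi_eta$offset,
    phi_eta_center = genome$phi_eta$center,
    phi_eta_width = genome$phi_eta$width)
}

#' Rebuild a genome from its canonical 22-vector
#'
#' @param x numeric vector of length 22, in the order of
#'   [genome_to_vector()] (names are ignored; position is authoritative).
#' @return an [nsa_genome()] object.
#' @export
genome_from_vector <- function(x) {
  if (length(x) != 22L) stop("a genome vector has exactly 22 entries", call. = FALSE)
  x <- as.numeric(x)
  nsa_genome(
    tau_u = x[1], tau_v = x[2], i_ext = x[3],
    dur_pre = x[4], dur_post = x[5], w_plus = x[6],
    resp_u = response_params(x[7], x[8], x[9]),
    resp_v = response_params(x[10], x[11], x[12]),
    phi_v = gaussian_sigmoid_params(x[13], x[14], x[15], x[16], x[17]),
    phi_eta = gaussian_sigmoid_params(x[18], x[19], x[20], x[21], x[22]))
}

#' Box constraints of the genome parameters
#'
#' Lower/upper bounds used by the evolution strategy. The phase durations
#' are constrained to \[400, 3000\] ms; the remaining ranges are generous
#' boxes bracketing the useful shapes of the response and weight-filter
#' functions (weights live in \[0, w_plus\], so offsets and centers may
#' range somewhat beyond that interval).
#'
#' @return a data.frame with columns `parameter`, `lower`, `upper`
#'   (22 rows, canonical order).
#' @export
genome_bounds <- function() {
  b <- rbind(
    tau_u = c(1, 500), tau_v = c(1, 500), i_ext = c(0.1, 5),
    dur_pre = c(400, 3000), dur_post = c(400, 3000), w_plus = c(0.1, 5),
    u_gain = c(0.1, 50), u_offset = c(-1, 2), u_threshold = c(0, 1),
    v_gain = c(0.1, 50), v_offset = c(-1, 2), v_threshold = c(0, 1),
    phi_v_alpha = c(0, 1), phi_v_slope = c(0.1, 50),
    phi_v_offset = c(-1, 2), phi_v_center = c(-1, 2),
    phi_v_width = c(0.01, 2),
    phi_eta_alpha = c(0, 1), phi_eta_slope = c(0.1, 50),
    phi_eta_offset = c(-1, 2), phi_eta_center = c(-1, 2),
    phi_eta_width = c(0.01, 2))
  data.frame(parameter = rownames(b), lower = b[, 1], upper = b[, 2],
             row.names = NULL)
}

#' Read / write a genome as JSON
#'
#' Genomes are stored as a flat JSON map of the 22 named scalars plus a
#' `schema_version` field.
#'
#' @param path file path.
#' @return `read_genome()` returns an [nsa_genome()]; `write_genome()`
#'   returns `path` invisibly.
#' @export
read_genome <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(.genome_fields, names(raw))
  if (length(missing)) {
    stop("genome file lacks fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  genome_from_vector(unlist(raw[.genome_fields]))
}

#' @rdname read_genome
#' @param genome an [nsa_genome()] object.
#' @export
write_genome <- function(genome, path) {
  v <- as.list(genome_to_vector(genome))
  v$schema_version <- 1L
  jsonlite::write_json(v, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default agent genome
#'
#' The genome shipped with the package, obtained by the package's own short
#' evolutionary search (see `evolve_genome()`) seeded from a hand-designed
#' starting point. The publication-scale evolved genome is not distributed;
#' this default is a working stand-in that exhibits the intended
#' explore/commit behavior at moderate arm counts.
#'
#' @return an [nsa_genome()] object.
#' @export
default_genome <- function() {
  read_genome(system.file("extdata", "genome_default.json",
                          package = "nsabandit", mustWork = TRUE))
}
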