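#' Generalized logistic sigmoid
#'
#' Logistic function `1 / (1 + exp(-gain * (x - offset)))`, the building
#' block of both neural response functions and the Gaussian-sigmoid weight
#' filters. For `gain > 0` it is monotone increasing in `x` and saturates
#' in (0, 1).
#'
#' @param x numeric vector of inputs.
#' @param gain steepness of the sigmoid.
#' @param offset midpoint: `generalized_sigmoid(offset, gain, offset)` is 0.5.
#' @return numeric vector of the same length as `x`, values in (0, 1).
#' @examples
#' generalized_sigmoid(1, gain = 2, offset = 0) # 1 / (1 + exp(-2))
#' @export
generalized_sigmoid <- function(x, gain, offset) {
  1 / (1 + exp(-gain * (x - offset)))
}

#' Parameters of a thresholded sigmoid neural response
#'
#' A population's firing-rate response is a generalized sigmoid gated by a
#' hard threshold: the sigmoid value passes through when it reaches
#' `threshold`, otherwise the response is 0. This yields a high-pass,
#' coincidence-detector style f-I curve while keeping the graded rate
#' information that argmax-based selection needs.
#'
#' @param gain sigmoid gain (finite).
#' @param offset sigmoid midpoint.
#' @param threshold gating threshold in \[0, 1\]; sigmoid outputs below it
#'   are silenced.
#' @return an object of class `response_params`.
#' @seealso [neural_response()]
#' @export
response_params <- function(gain, offset, threshold) {
  stopifnot(is.finite(gain), is.finite(offset), is.finite(threshold))
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(gain = gain, offset = offset, threshold = threshold),
            class = "response_params")
}

#' Thresholded sigmoid neural response
#'
#' @param x numeric vector of membrane activities.
#' @param params a [response_params()] object.
#' @return numeric vector in \[0, 1\]: the sigmoid value where it is at
#'   least `params$threshold`, 0 elsewhere.
#' @examples
#' p <- response_params(gain = 10, offset = 0.5, threshold = 0.6)
#' neural_response(0.6, p) # sigmoid(1) ~ 0.731, passes the 0.6 gate
#' @export
neural_response <- function(x, params) {
  s <- generalized_sigmoid(x, params$gain, params$offset)
  s * (s >= params$threshold)
}

#' Parameters of a Gaussian-sigmoid mixture
#'
#' Weighted sum of a generalized sigmoid and a Gaussian bump,
#' `(1 - alpha) * sigmoid(x; slope, offset) + alpha * exp(-(x - center)^2 / (2 width^2))`.
#' The two components contribute complementary traits: the sigmoid saturates
#' on one side of its midpoint, the Gaussian is tuned to a range. The same
#' family parameterizes both the option-value filter applied to the plastic
#' weights and the weight-dependent learning-rate function.
#'
#' @param alpha mixing weight in \[0, 1\] of the Gaussian component.
#' @param slope sigmoid steepness.
#' @param offset sigmoid midpoint.
#' @param center Gaussian mean.
#' @param width Gaussian standard deviation (> 0).
#' @return an object of class `gaussian_sigmoid_params`.
#' @export
gaussian_sigmoid_params <- function(alpha, slope, offset, center, width) {
  if (!is.finite(width) || width <= 0) {
    stop("`width` must be a positive finite number", call. = FALSE)
  }
  if (alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(alpha = alpha, slope = slope, offset = offset,
                 center = center, width = width),
            class = "gaussian_sigmoid_params")
}

#' Gaussian-sigmoid mixture function
#'
#' @param x numeric vector (typically synaptic weights).
#' @param params a [gaussian_sigmoid_params()] object.
#' @return numeric vector in \[0, 1\].
#' @examples
#' p <- gaussian_sigmoid_params(alpha = 1, slope = 1, offset = 0,
#'                              center = 0.2, width = 0.1)
#' gaussian_sigmoid(0.2, p) # Gaussian peak -> 1
#' @export
gaussian_sigmoid <- function(x, params) {
  (1 - params$alpha) *
    generalized_sigmoid(x, params$slope, params$offset) +
    params$alpha * exp(-(x - params$center)^2 / (2 * params$width^2))
}
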