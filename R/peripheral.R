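#' Peripheral afferent spread model
#'
#' Mechanical stimulation of one finger also excites tactile afferents
#' terminating on neighbouring fingers, so even "single-finger" input is
#' distributed across the hand. This parametric stand-in for a full
#' spiking-afferent simulation pools the afferent drive per finger and lets
#' it decay exponentially with distance on the finger index:
#' \deqn{S_{ij} = \exp(-|i-j|/\lambda)}
#' Column \code{j} gives the pooled drive to every finger's afferents when
#' finger \code{j} is stimulated. \code{lambda = 0} gives the identity (no
#' spread). The default \code{lambda} puts the nearest neighbour at 30\% of
#' the self-drive.
#'
#' @param lambda spread length scale in finger-index units, \code{>= 0}.
#' @return a 5 x 5 matrix of class \code{"spread_model"} with unit diagonal;
#'   \code{attr(, "lambda")} records the scale.
#' @export
#' @examples
#' S <- build_spread(-1 / log(0.3))
#' S["D1", "D2"]  # 0.3
build_spread <- function(lambda = -1 / log(0.3)) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0)
    stop("domain error: lambda must be a single real >= 0")
  d <- abs(outer(1:5, 1:5, "-"))
  S <- if (lambda == 0) (d == 0) * 1 else exp(-d / lambda)
  dimnames(S) <- list(finger = finger_labels(), condition = finger_labels())
  attr(S, "lambda") <- lambda
  class(S) <- c("spread_model", class(S))
  S
}

#' Pooled peripheral drives under single-finger stimulation
#'
#' Assembles, for each of the five single-finger stimulation conditions, the
#' 5-vector of pooled afferent drives implied by a spread model. Each column
#' is one stimulation condition; each row one finger's afferent pool.
#'
#' @param spread a \code{spread_model} from [build_spread()].
#' @param session \code{"baseline"} or \code{"block"}; for \code{"block"} the
#'   blocked finger's drive is attenuated via [apply_block()].
#' @param blocked_finger finger label, used when \code{session = "block"}.
#' @param fraction residual drive fraction under block.
#' @return a 5 x 5 matrix of class \code{"peripheral_drives"} (finger x
#'   condition) with a \code{"session"} attribute.
#' @export
peripheral_drives <- function(spread = build_spread(),
                              session = c("baseline", "block"),
                              blocked_finger = "D2",
                              fraction = 0.2) {
  session <- match.arg(session)
  D <- matrix(as.numeric(spread), 5, 5,
              dimnames = list(finger = finger_labels(),
                              condition = finger_labels()))
  attr(D, "session") <- "baseline"
  class(D) <- c("peripheral_drives", "matrix", "array")
  if (session == "block")
    D <- apply_block(D, blocked_finger, fraction)
  D
}

#' Apply a single-finger nerve block to peripheral drives
#'
#' Simulates anaesthesia of one finger by multiplying that finger's pooled
#' afferent drive by \code{fraction} in every stimulation condition; a
#' fraction of 0.2 leaves 20\% residual activation, modelling the small
#' residual input that survives a ring block. All other fingers' drives are
#' untouched.
#'
#' @param drives a \code{peripheral_drives} matrix (finger x condition).
#' @param finger finger label to block, e.g. \code{"D2"}.
#' @param fraction residual fraction in \code{[0, 1]}.
#' @return the modified \code{peripheral_drives}, with
#'   \code{attr(, "session") == "block"}.
#' @export
apply_block <- function(drives, finger, fraction) {
  if (!finger %in% finger_labels())
    stop("domain error: unknown finger label '", finger, "'")
  if (fraction < 0 || fraction > 1)
    stop("domain error: fraction must lie in [0, 1]")
  drives[finger, ] <- drives[finger, ] * fraction
  attr(drives, "session") <- "block"
  attr(drives, "blocked_finger") <- finger
  attr(drives, "fraction") <- fraction
  drives
}
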