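# Quadrature-mirror filter pairs underlying the discrete non-decimated wavelets.

# Daubechies extremal-phase low-pass coefficients, orders 1-10 (order = number
# of vanishing moments, filter length 2*order). Standard published values.
.daub_lo <- list(
  c(0.70710678118654757, 0.70710678118654757),
  c(0.48296291314453416, 0.83651630373780794, 0.22414386804201339,
    -0.12940952255126037),
  c(0.33267055295008263, 0.80689150931109255, 0.45987750211849154,
    -0.13501102001025458, -0.085441273882026658, 0.035226291885709533),
  c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
    -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
    0.032883011666885197, -0.010597401785069032),
  c(0.16010239797419293, 0.60382926979718965, 0.72430852843777294,
    0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
    0.077571493840045719, -0.0062414902127982744, -0.012580751999081999,
    0.0033357252854737712),
  c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536,
    0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
    0.097501605587323043, 0.027522865530305727, -0.03158203931748603,
    0.00055384220116149613, 0.0047772575109455108, -0.0010773010853084796),
  c(0.077852054085009184, 0.39653931948191729, 0.72913209084623509,
    0.46978228740519312, -0.14390600392856498, -0.22403618499387498,
    0.071309219266830259, 0.080612609151083078, -0.038029936935014413,
    -0.016574541630666881, 0.01255099855609984, 0.00042957797292136651,
    -0.0018016407040474908, 0.00035371379997452024),
  c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976,
    0.58535468365420673, -0.015829105256349306, -0.28401554296154691,
    0.00047248457391328279, 0.12874742662047847, -0.017369301001807547,
    -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766,
    -0.0048703529934515741, -0.00039174037337694705, 0.00067544940645056933,
    -0.00011747678412476953),
  c(0.038077947363878345, 0.24383467461259034, 0.60482312369011115,
    0.65728807805130052, 0.13319738582500756, -0.29327378327917492,
    -0.096840783222976456, 0.14854074933810638, 0.03072568147933338,
    -0.067632829061329974, 0.00025094711483145197, 0.022361662123679096,
    -0.0047232047577513972, -0.0042815036824634303, 0.0018476468830562265,
    0.00023038576352319597, -0.00025196318894271012, 3.9347320316271603e-05),
  c(0.026670057900555554, 0.1881768000776915, 0.52720118893172563,
    0.68845903945360354, 0.28117234366057747, -0.24984642432731538,
    -0.19594627437737705, 0.12736934033579325, 0.093057364603572348,
    -0.071394147166397082, -0.029457536821875813, 0.033212674059341002,
    0.0036065535669561697, -0.010733175483330575, 0.0013953517470529011,
    0.0019924052951850561, -0.00068585669495971162, -0.00011646685512928545,
    9.3588670320069592e-05, -1.3264202894521244e-05)
)

#' Wavelet filter pair
#'
#' Construct the low-/high-pass quadrature-mirror filter pair for a supported
#' wavelet family. These filters generate the discrete non-decimated wavelets
#' used throughout the package.
#'
#' @param family `"haar"` or `"daubechies"` (extremal-phase). `"haar"` is an
#'   alias for Daubechies order 1. Additional families can be supplied as a
#'   plain JSON table via `file` (an object mapping names to low-pass
#'   coefficient arrays).
#' @param number filter order for `"daubechies"` (1 to 10; filter length is
#'   twice the order). Ignored for `"haar"`.
#' @param file optional path to a JSON table of extra low-pass filters.
#' @return An object of class `"ls2w_filter"`: a list with elements `family`,
#'   `number`, `lo` (low-pass coefficients, unit sum of squares) and `hi`
#'   (quadrature-mirror high-pass, zero sum).
#' @examples
#' f <- ls2w_filter("haar")
#' sum(f$lo^2)  # 1
#' sum(f$hi)    # 0
#' @export
ls2w_filter <- function(family = c("haar", "daubechies"), number = 1,
                        file = NULL) {
  if (!is.null(file)) {
    tab <- jsonlite::read_json(file, simplifyVector = TRUE)
    if (is.null(tab[[family]]))
      stop("filter family '", family, "' not found in ", file)
    lo <- as.numeric(tab[[family]])
  } else {
    family <- match.arg(family)
    if (family == "haar") {
      number <- 1L
      lo <- .daub_lo[[1L]]
    } else {
      if (!(is.numeric(number) && length(number) == 1L &&
            number == round(number) && number >= 1 && number <= 10))
        stop("unsupported Daubechies order: ", number,
             " (orders 1-10 are available)")
      lo <- .daub_lo[[as.integer(number)]]
    }
  }
  if (abs(sum(lo^2) - 1) > 1e-10)
    stop("low-pass filter is not normalised (sum of squares must be 1)")
  L <- length(lo)
  hi <- (-1)^(seq_len(L) - 1) * rev(lo)   # quadrature mirror
  structure(list(family = family, number = as.integer(number),
                 lo = lo, hi = hi),
            class = "ls2w_filter")
}

#' @export
print.ls2w_filter <- function(x, ...) {
  cat("Wavelet filter pair: ", x$family,
      if (x$family != "haar") paste0(" (order ", x$number, ")"),
      ", length ", length(x$lo), "\n", sep = "")
  invisible(x)
}
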