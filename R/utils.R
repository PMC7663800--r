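# unit conversion constant shared across modules; the simulator works in
# mmHg at its interface and MPa internally
.MMHG_TO_MPA <- 1.33322e-4

# gas constant in J kmol^-1 K^-1 so that |C10|/(R*T) with C10 in Pa lands
# in kmol/m^3
.GAS_CONSTANT <- 8314

#' Convert pressure between mmHg and MPa
#'
#' @param p numeric vector of pressures.
#' @return Converted numeric vector (1 mmHg = 1.33322e-4 MPa).
#' @examples
#' mmhg_to_mpa(100)
#' mpa_to_mmhg(mmhg_to_mpa(100))
#' @export
mmhg_to_mpa <- function(p) p * .MMHG_TO_MPA

#' @rdname mmhg_to_mpa
#' @export
mpa_to_mmhg <- function(p) p / .MMHG_TO_MPA

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL evaluates as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

stop_pugraft <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pugraft_error")))
}

check_scalar_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_pugraft(sprintf("`%s` must be a single number", name), "pugraft_value_error")
  }
  if (finite && !is.finite(x)) {
    stop_pugraft(sprintf("`%s` must be finite", name), "pugraft_value_error")
  }
  if (positive && x <= 0) {
    stop_pugraft(sprintf("`%s` must be > 0", name), "pugraft_value_error")
  }
  invisible(x)
}
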