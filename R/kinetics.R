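#' Gating kinetics parameter table
#'
#' Loads the channel-gating kinetics table shipped with the package
#' (`inst/extdata/gating_kinetics.csv`), one record per (gate, role).
#' Gates `m`, `h` (Na), `n` (delayed-rectifier K), `a`, `ha` (A-type K) and
#' `c` (Ca) are parameterized by `alpha`/`beta` rate records; gates `q`
#' (HCN) and `tm`, `th` (T-type Ca) by `inf`/`tau` records.
#'
#' @param path Optional path to an alternative kinetics file with the same
#'   schema (`gate,role,form,p1..p4`).
#' @return A data.frame with columns `gate`, `role`, `form`, `p1`..`p4`.
#' @export
kinetics_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.rgcstim_env$kin_tab)) return(.rgcstim_env$kin_tab)
    path <- system.file("extdata", "gating_kinetics.csv", package = "rgcstim")
    tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    .rgcstim_env$kin_tab <- tab
    return(tab)
  }
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @noRd
gate_names <- function() c("m", "h", "n", "a", "ha", "c", "q", "tm", "th")

form_code <- function(form) {
  switch(form,
    linexp = 1L, expdec = 2L, sigmoid = 3L,
    siginf = 4L, taugauss = 5L,
    stop("unknown rate form: ", form)
  )
}

#' Pack the kinetics table into the 9 x 10 numeric matrix used by the solver
#' @noRd
kinetics_matrix <- function(tab = kinetics_table()) {
  gates <- gate_names()
  kin <- matrix(0, nrow = length(gates), ncol = 10,
                dimnames = list(gates, NULL))
  for (g in gates) {
    rows <- tab[tab$gate == g, , drop = FALSE]
    if (nrow(rows) != 2) stop("kinetics table must have 2 records for gate ", g)
    if (all(c("alpha", "beta") %in% rows$role)) {
      ra <- rows[rows$role == "alpha", ]
      rb <- rows[rows$role == "beta", ]
    } else if (all(c("inf", "tau") %in% rows$role)) {
      ra <- rows[rows$role == "inf", ]
      rb <- rows[rows$role == "tau", ]
    } else {
      stop("gate ", g, " must be given as alpha/beta or inf/tau records")
    }
    kin[g, ] <- c(form_code(ra$form), ra$p1, ra$p2, ra$p3, ra$p4,
                  form_code(rb$form), rb$p1, rb$p2, rb$p3, rb$p4)
  }
  kin
}

eval_rate_form <- function(form, V, p) {
  switch(form,
    linexp = {
      x <- V - p[2]
      d <- x / p[3]
      ifelse(abs(d) < 1e-7, p[1] * p[3] * (1 + d / 2),
             p[1] * x / (1 - exp(-d)))
    },
    expdec = p[1] * exp(-(V - p[2]) / p[3]),
    sigmoid = p[1] / (1 + exp(-(V - p[2]) / p[3])),
    stop("unknown rate form: ", form)
  )
}

#' Voltage-dependent opening and closing rates of a gating variable
#'
#' Evaluates the forward (`alpha`) and backward (`beta`) rate constants of a
#' gate at membrane voltage `V`.  For gates parameterized by steady state and
#' time constant, the equivalent rates `alpha = inf/tau`,
#' `beta = (1 - inf)/tau` are returned.  Removable singularities of the
#' linear-exponential forms are evaluated by their analytic limit.
#'
#' @param gate One of `"m"`, `"h"`, `"n"`, `"a"`, `"ha"`, `"c"`, `"q"`,
#'   `"tm"`, `"th"`.
#' @param V Membrane voltage in mV (vectorized).
#' @param tab Kinetics table (defaults to the shipped one).
#' @return A list with numeric vectors `alpha` and `beta` in 1/ms.
#' @export
rate_functions <- function(gate, V, tab = kinetics_table()) {
  stopifnot(all(is.finite(V)))
  if (!gate %in% gate_names()) stop("unknown gate: ", gate)
  rows <- tab[tab$gate == gate, , drop = FALSE]
  if (all(c("alpha", "beta") %in% rows$role)) {
    ra <- rows[rows$role == "alpha", ]
    rb <- rows[rows$role == "beta", ]
    alpha <- eval_rate_form(ra$form, V, as.numeric(ra[, c("p1", "p2", "p3", "p4")]))
    beta <- eval_rate_form(rb$form, V, as.numeric(rb[, c("p1", "p2", "p3", "p4")]))
  } else {
    ri <- rows[rows$role == "inf", ]
    rt <- rows[rows$role == "tau", ]
    xinf <- 1 / (1 + exp((V - ri$p1) / ri$p2))
    tau <- rt$p1 + rt$p2 * exp(-((V - rt$p3) / rt$p4)^2)
    alpha <- xinf / tau
    beta <- (1 - xinf) / tau
  }
  list(alpha = alpha, beta = beta)
}

#' Steady-state activation of a gate
#'
#' @inheritParams rate_functions
#' @return `alpha / (alpha + beta)`, in [0, 1].
#' @export
gate_steady_state <- function(gate, V, tab = kinetics_table()) {
  r <- rate_functions(gate, V, tab)
  r$alpha / (r$alpha + r$beta)
}
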