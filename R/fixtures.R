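# Bundled models and a seeded random-model generator, so every module is
# testable without downloads.

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "bnscreen")
  if (!nzchar(path)) stop(sprintf("bundled fixture '%s' is missing", file),
                          call. = FALSE)
  path
}

#' The 9-node example network
#'
#' A fictive task-control network: a `do` instruction and a `factory` are
#' constant inputs; the factory supplies `energy`; a `locker` must stop the
#' `task` whenever energy is missing. The pathological variant constitutively
#' inactivates the locker (`locker = 0`), so the task no longer considers
#' whether energy is available.
#'
#' @return List with elements `physio` and `patho` (both `variant`s over the
#'   same 9-node Boolean model).
#' @examples
#' ex <- example_network()
#' length(ex$physio$model$nodes) # 9
#' @export
example_network <- function() {
  model <- read_model(fixture_path("example_physio.txt"))
  physio <- apply_forcings(model, label = "physiological")
  patho <- apply_forcings(model,
                          parse_forcings(readLines(fixture_path("example_patho_forcings.txt"))),
                          label = "pathological")
  list(physio = physio, patho = patho)
}

#' The bladder-tumorigenesis case-study model (synthetic reconstruction)
#'
#' A 27-node Boolean working model of bladder tumorigenesis: growth-factor
#' receptor signalling (EGFR, FGFR3, RAS, PI3K/AKT), the CDKN2A products
#' p14ARF and p16INK4a, and the cell-cycle core (cyclins, CDC25A, E2F1/E2F3,
#' RB1/RBL2, p21CIP), with the DNA-damage arm (ATM, CHEK1/2, TP53, MDM2)
#' quiescent under the bundled input configuration (growth stimulation and
#' growth inhibition present, no DNA damage; inputs injected into the
#' equations). Ternary variables are encoded as exact-level Boolean pairs.
#' The pathological variant deletes CDKN2A: `p14ARF = 0`, `p16INK4a = 0`.
#'
#' The bundled equations are a validated reconstruction of the published
#' model this case study derives from, not the original file (see the files
#' `bladder_synthetic_*.txt` and the package vignette).
#'
#' @param inputs_injected When `FALSE`, return the pre-injection 31-node
#'   model instead (inputs as self-equations), for exercising
#'   [substitute_inputs()].
#' @return List with elements `physio`, `patho` (variants) and `readouts`
#'   (a `readout_set`: Proliferation, GrowthArrest, Apoptosis); for the
#'   pre-injection form additionally `inputs` (the injection forcings).
#' @export
bladder_model <- function(inputs_injected = TRUE) {
  if (!inputs_injected) {
    full <- read_model(fixture_path("bladder_synthetic_full.txt"))
    inputs <- parse_forcings(readLines(fixture_path("bladder_synthetic_inputs.txt")))
    return(list(model = full, inputs = inputs))
  }
  model <- read_model(fixture_path("bladder_synthetic_physio.txt"))
  physio <- apply_forcings(model, label = "physiological")
  patho <- apply_forcings(model,
                          parse_forcings(readLines(fixture_path("bladder_synthetic_forcings.txt"))),
                          label = "pathological")
  readouts <- read_readouts(fixture_path("bladder_synthetic_readouts.txt"), model)
  list(physio = physio, patho = patho, readouts = readouts)
}

#' Generate a random logical model
#'
#' Substrate for property tests against exhaustive oracles: each node gets a
#' random connective tree of bounded depth over at most `max_in_degree`
#' uniformly chosen regulators. Reproducible under `set.seed()`.
#'
#' @param n Number of nodes.
#' @param max_in_degree Maximum regulators per node.
#' @param h Number of logic levels.
#' @param depth Maximum expression-tree depth (0 gives a bare variable or
#'   constant rule).
#' @param seed Optional seed.
#' @return A `logical_model`.
#' @examples
#' random_model(5, seed = 1)
#' @export
random_model <- function(n, max_in_degree = 3L, h = 2L, depth = 2L, seed = NULL) {
  stopifnot(n >= 1, max_in_degree >= 1)
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("x%d", seq_len(n))
  levels <- (0:(h - 1L)) / (h - 1L)
  rand_expr <- function(d, regs) {
    if (d <= 0 || stats::runif(1) < 0.3) {
      if (stats::runif(1) < 0.1) return(e_const(sample(levels, 1L)))
      return(e_var(sample(regs, 1L)))
    }
    switch(sample(c("not", "and", "or"), 1L),
      not = e_not(rand_expr(d - 1L, regs)),
      and = list(op = "and", args = list(rand_expr(d - 1L, regs),
                                         rand_expr(d - 1L, regs))),
      or = list(op = "or", args = list(rand_expr(d - 1L, regs),
                                       rand_expr(d - 1L, regs)))
    )
  }
  exprs <- lapply(nodes, function(nm) {
    k <- sample.int(min(max_in_degree, n), 1L)
    regs <- sample(nodes, k)
    rand_expr(depth, regs)
  })
  names(exprs) <- nodes
  logical_model(exprs, h = h)
}
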