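#' Population specification
#'
#' Describes one neural mass population: its membrane/synaptic time constant,
#' synaptic gain, sigmoid slope, and intrinsic noise. The nine populations of
#' the circuit are the four motor-cortex microcircuit layers (superficial,
#' middle and deep pyramidal cells plus inhibitory interneurons) and the five
#' subcortical populations (striatum, external and internal pallidum,
#' subthalamic nucleus, ventrolateral thalamus).
#'
#' @param id population label, one of `"M2.SP"`, `"M2.MP"`, `"M2.DP"`,
#'   `"M2.II"`, `"STR"`, `"GPe"`, `"STN"`, `"GPi"`, `"Thal"`.
#' @param sign `"excitatory"` or `"inhibitory"`; sets the sign with which the
#'   population's output enters its targets.
#' @param tau membrane/synaptic time constant in seconds (> 0).
#' @param gain synaptic gain H in millivolts.
#' @param slope sigmoid slope parameter of the activation function (> 0).
#' @param noise_sd standard deviation of the intrinsic stochastic input
#'   (input units); zero for populations without intrinsic noise.
#' @param noise_scale dimensionless multiplier applied to the intrinsic input.
#' @return A one-row `data.frame` with the population parameters.
#' @export
population_spec <- function(id, sign, tau, gain, slope,
                            noise_sd = 0, noise_scale = 1) {
  stopifnot(is.character(id), length(id) == 1L)
  sign <- match.arg(sign, c("excitatory", "inhibitory"))
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (!is.finite(slope) || slope <= 0) stop("slope must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  data.frame(id = id, sign = sign, tau = tau, gain = gain, slope = slope,
             noise_sd = noise_sd, noise_scale = noise_scale,
             stringsAsFactors = FALSE)
}

#' Population labels of the circuit, in canonical order
#' @keywords internal
cbgt_populations <- function() {
  c("M2.SP", "M2.MP", "M2.DP", "M2.II", "STR", "GPe", "STN", "GPi", "Thal")
}

#' Source labels of the circuit, in canonical order
#' @return Character vector of the six observed sources.
#' @export
cbgt_sources <- function() c("M2", "STR", "GPe", "STN", "GPi", "Thal")

#' Default circuit parameterization
#'
#' Builds the packaged default cortico-basal ganglia-thalamic circuit: six
#' sources (M2 microcircuit, STR, GPe, STN, GPi, Thal) and nine populations.
#' The six-source connectivity follows the standard motor-loop wiring
#' (hyperdirect cortex to STN, indirect striatum to GPe, reciprocal STN/GPe,
#' striatal and subthalamic convergence on GPi, pallido-thalamic inhibition
#' and thalamo-cortical feedback). The default parameter values are a tuned
#' surrogate for a fitted Parkinsonian model: the reciprocal STN/GPe loop
#' resonates in the low beta band so the subthalamic signal carries
#' transient 14-21 Hz bursts; details of the tuning are in the package
#' vignette. Intrinsic stochastic inputs drive the subcortical populations
#' and the middle pyramidal layer only.
#'
#' @return An object of class `cbgt_circuit`: a list with elements
#'   `populations` (data frame of [population_spec()] rows), `inter` (signed
#'   source-level connections with delays in seconds), `intra` (cortical
#'   microcircuit connections, including per-layer self-inhibition),
#'   `output_map` (source -> population whose sigmoid output projects to
#'   other sources), and `observation_map` (source -> observed population).
#' @export
#' @examples
#' circ <- cbgt_circuit()
#' circuit_matrices(circ)$inter_weights
cbgt_circuit <- function() {
  pops <- rbind(
    population_spec("M2.SP", "excitatory", tau = 0.008, gain = 12, slope = 3),
    population_spec("M2.MP", "excitatory", tau = 0.005, gain = 12, slope = 3,
                    noise_sd = 1.50),
    population_spec("M2.DP", "excitatory", tau = 0.008, gain = 12, slope = 3),
    population_spec("M2.II", "inhibitory", tau = 0.008, gain = 10, slope = 3),
    population_spec("STR",   "inhibitory", tau = 0.010, gain = 10, slope = 3,
                    noise_sd = 0.05),
    population_spec("GPe",   "inhibitory", tau = 0.006, gain = 15, slope = 3,
                    noise_sd = 0.05),
    population_spec("STN",   "excitatory", tau = 0.005, gain = 15, slope = 3,
                    noise_sd = 0.05),
    population_spec("GPi",   "inhibitory", tau = 0.005, gain = 10, slope = 3,
                    noise_sd = 0.10),
    population_spec("Thal",  "excitatory", tau = 0.005, gain = 10, slope = 3,
                    noise_sd = 0.10)
  )

  # source-level connections; weight magnitudes, sign applied from source sign.
  # the reciprocal STN/GPe pair is tuned near-critical so the loop resonates
  # in low beta; the cortex is the dominant stochastic driver (via M2.MP)
  inter <- data.frame(
    from   = c("Thal", "M2",  "STR", "STN", "M2",  "GPe", "STR", "STN", "GPi"),
    to     = c("M2",   "STR", "GPe", "GPe", "STN", "STN", "GPi", "GPi", "Thal"),
    weight = c(16,     4,     20,    35,    30,    25,    10,    25,    25),
    delay  = c(0.003,  0.008, 0.008, 0.004, 0.004, 0.004, 0.008, 0.003, 0.003),
    stringsAsFactors = FALSE
  )

  # M2 microcircuit: Thal drives MP (handled by inter via target map), MP -> SP,
  # SP -> DP, SP <-> II, per-layer self-inhibition; DP projects to subcortex
  intra <- data.frame(
    from   = c("M2.MP", "M2.SP", "M2.SP", "M2.II", "M2.SP", "M2.MP", "M2.DP"),
    to     = c("M2.SP", "M2.DP", "M2.II", "M2.SP", "M2.SP", "M2.MP", "M2.DP"),
    weight = c(15,      20,      8,       8,       5,       5,       5),
    delay  = rep(0.002, 7),
    stringsAsFactors = FALSE
  )

  structure(list(
    populations = pops,
    inter = inter,
    intra = intra,
    # population receiving each source's afferents, and the population whose
    # output projects onwards, per source
    input_map = c(M2 = "M2.MP", STR = "STR", GPe = "GPe", STN = "STN",
                  GPi = "GPi", Thal = "Thal"),
    output_map = c(M2 = "M2.DP", STR = "STR", GPe = "GPe", STN = "STN",
                   GPi = "GPi", Thal = "Thal"),
    observation_map = c(M2 = "M2.SP", STR = "STR", GPe = "GPe", STN = "STN",
                        GPi = "GPi", Thal = "Thal")
  ), class = "cbgt_circuit")
}

pop_sign <- function(circuit, id) {
  s <- circuit$populations$sign[match(id, circuit$populations$id)]
  ifelse(s == "inhibitory", -1, 1)
}

source_of_pop <- function(id) {
  ifelse(startsWith(id, "M2."), "M2", id)
}

#' Source- and population-level coupling matrices
#'
#' Expands a circuit into the signed 6x6 source-level weight and delay
#' matrices (rows = target, columns = source) and the signed 9x9
#' population-level matrices actually integrated. Inhibitory sources and
#' self-inhibitory microcircuit connections enter with negative weight.
#'
#' @param circuit a [cbgt_circuit()] object.
#' @return List with `inter_weights`, `inter_delays` (6x6, source level) and
#'   `W`, `D` (9x9, population level, delays in seconds).
#' @export
circuit_matrices <- function(circuit) {
  src <- cbgt_sources()
  pop <- circuit$populations$id
  iw <- matrix(0, 6, 6, dimnames = list(src, src))
  id <- matrix(0, 6, 6, dimnames = list(src, src))
  W <- matrix(0, 9, 9, dimnames = list(pop, pop))
  D <- matrix(0, 9, 9, dimnames = list(pop, pop))
  for (k in seq_len(nrow(circuit$inter))) {
    cn <- circuit$inter[k, ]
    sgn <- pop_sign(circuit, circuit$output_map[[cn$from]])
    iw[cn$to, cn$from] <- sgn * cn$weight
    id[cn$to, cn$from] <- cn$delay
    pfrom <- circuit$output_map[[cn$from]]
    pto <- circuit$input_map[[cn$to]]
    W[pto, pfrom] <- sgn * cn$weight
    D[pto, pfrom] <- cn$delay
  }
  for (k in seq_len(nrow(circuit$intra))) {
    cn <- circuit$intra[k, ]
    sgn <- if (cn$from == cn$to) -1 else pop_sign(circuit, cn$from)
    W[cn$to, cn$from] <- sgn * cn$weight
    D[cn$to, cn$from] <- cn$delay
  }
  list(inter_weights = iw, inter_delays = id, W = W, D = D)
}

#' Validate a circuit object
#'
#' Checks the structural invariants: positive time constants and slopes,
#' non-negative noise with intrinsic noise on exactly the subcortical
#' populations plus the middle pyramidal layer, strictly positive delays on
#' every nonzero connection, and the canonical sparsity pattern of the
#' source-level connectivity (nonzero entries only at Thal->M2, M2->STR,
#' STR->GPe, STN->GPe, M2->STN, GPe->STN, STR->GPi, STN->GPi, GPi->Thal).
#'
#' @param circuit a [cbgt_circuit()] object.
#' @return The circuit, invisibly; errors describe the violated invariant.
#' @export
validate_circuit <- function(circuit) {
  p <- circuit$populations
  if (!identical(p$id, cbgt_populations()))
    stop("populations must be the nine canonical populations in order")
  if (any(p$tau <= 0)) stop("all tau must be > 0")
  if (any(p$slope <= 0)) stop("all slope must be > 0")
  if (any(p$noise_sd < 0)) stop("noise_sd must be >= 0")
  noisy <- p$id[p$noise_sd > 0]
  expected <- c("M2.MP", "STR", "GPe", "STN", "GPi", "Thal")
  if (!setequal(noisy, expected))
    stop("intrinsic noise must drive exactly the subcortical populations and M2.MP")
  m <- circuit_matrices(circuit)
  # model variants may remove connections, but never add new ones
  allowed <- rbind(c(1, 6), c(2, 1), c(3, 2), c(3, 4), c(4, 1), c(4, 3),
                   c(5, 2), c(5, 4), c(6, 5))
  nz <- which(m$inter_weights != 0, arr.ind = TRUE)
  key <- function(x) paste(x[, 1], x[, 2])
  if (!all(key(nz) %in% key(allowed)))
    stop("source-level connectivity violates the canonical sparsity pattern")
  if (any(m$inter_delays[m$inter_weights != 0] <= 0))
    stop("delays must be > 0 wherever the weight is nonzero")
  if (any(m$D[m$W != 0] <= 0))
    stop("population-level delays must be > 0 wherever the weight is nonzero")
  inhib <- p$id[p$sign == "inhibitory"]
  for (j in inhib) if (any(m$W[, j] > 0))
    stop("inhibitory source ", j, " must enter targets with negative weight")
  invisible(circuit)
}

#' Scale a subthalamic input pathway
#'
#' Multiplies the weight magnitude of either the hyperdirect (HD, cortex to
#' STN) or pallido-subthalamic (PS, GPe to STN) pathway, the two connections
#' whose reorganization characterizes the Parkinsonian network states.
#'
#' @param circuit a [cbgt_circuit()] object.
#' @param pathway `"HD"` or `"PS"`.
#' @param multiplier positive scale factor applied to the fitted weight.
#' @return The modified circuit.
#' @export
set_pathway_weight <- function(circuit, pathway = c("HD", "PS"), multiplier) {
  pathway <- match.arg(pathway)
  if (!is.finite(multiplier) || multiplier <= 0)
    stop("multiplier must be > 0")
  from <- if (pathway == "HD") "M2" else "GPe"
  k <- which(circuit$inter$from == from & circuit$inter$to == "STN")
  stopifnot(length(k) == 1L)
  circuit$inter$weight[k] <- circuit$inter$weight[k] * multiplier
  circuit
}

#' Read/write a circuit as YAML
#'
#' Round-trippable YAML serialization of the full parameterization
#' (populations, source-level connections, cortical microcircuit, maps).
#'
#' @param circuit a [cbgt_circuit()] object.
#' @param path file path.
#' @return `read_circuit_yaml` returns the circuit; `write_circuit_yaml`
#'   returns `path` invisibly.
#' @export
write_circuit_yaml <- function(circuit, path) {
  obj <- list(
    populations = lapply(seq_len(nrow(circuit$populations)), function(i)
      as.list(circuit$populations[i, ])),
    inter = lapply(seq_len(nrow(circuit$inter)), function(i)
      as.list(circuit$inter[i, ])),
    intra = lapply(seq_len(nrow(circuit$intra)), function(i)
      as.list(circuit$intra[i, ])),
    input_map = as.list(circuit$input_map),
    output_map = as.list(circuit$output_map),
    observation_map = as.list(circuit$observation_map)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_circuit_yaml
#' @export
read_circuit_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  bind_rows <- function(x) do.call(rbind, lapply(x, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  circ <- structure(list(
    populations = bind_rows(obj$populations),
    inter = bind_rows(obj$inter),
    intra = bind_rows(obj$intra),
    input_map = unlist(obj$input_map),
    output_map = unlist(obj$output_map),
    observation_map = unlist(obj$observation_map)
  ), class = "cbgt_circuit")
  validate_circuit(circ)
}

#' @export
print.cbgt_circuit <- function(x, ...) {
  cat("<cbgt_circuit> 6 sources / 9 populations\n")
  cat("  inter-source connections:", nrow(x$inter),
      "| intra-cortical:", nrow(x$intra), "\n")
  hd <- x$inter$weight[x$inter$from == "M2" & x$inter$to == "STN"]
  ps <- x$inter$weight[x$inter$from == "GPe" & x$inter$to == "STN"]
  cat(sprintf("  pathway weights: HD (M2->STN) %.3f, PS (GPe->STN) %.3f\n",
              hd, ps))
  invisible(x)
}
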