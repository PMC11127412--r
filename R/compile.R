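# Transition-rate evaluation: reference interpreter and compiled paths.

#' Per-node transition rates in a state
#'
#' The rate of node `i` is `rate_up[i]` when the node is inactive and its
#' logic evaluates to 1, `rate_down[i]` when it is active and its logic
#'
#' evaluates to 0, and exactly 0 when the logic agrees with the current
#' value (the node cannot flip; a state where all rates vanish is a fixed
#' point). This is the reference AST-interpreter path; [compile_model()]
#' produces equivalent compiled evaluators.
#'
#' @param network a `boolean_network` with numeric (resolved) rates.
#' @param state packed state bitmask.
#' @return numeric vector of length `n`; `sum()` of it is the total exit
#'   rate of the state.
#' @export
transition_rates <- function(network, state) {
  vapply(seq_len(network$n), function(i) {
    nd <- network$nodes[[i]]
    si <- bit_get(state, i - 1L)
    fi <- evaluate_formula(nd$logic, state)
    if (si == fi) 0 else if (si == 1L) nd$rate_down else nd$rate_up
  }, numeric(1))
}

require_numeric_rates <- function(network) {
  for (nd in network$nodes) {
    if (is.character(nd$rate_up) || is.character(nd$rate_down)) {
      stop(
        "node '", nd$name, "' has unresolved $param rates; ",
        "apply a configuration with parse_cfg() first"
      )
    }
  }
  invisible(network)
}

# generate R source for the full rate-vector function; the formula
# structure is transcribed verbatim (no constant folding or
# simplification), so generated code size tracks formula size
codegen_r <- function(network) {
  n <- network$n
  used <- sort(unique(unlist(lapply(network$nodes, function(nd) {
    collect_indices(nd$logic)
  }))))
  lines <- c("function(state) {")
  for (i in used) {
    lines <- c(lines, sprintf(
      "  b%d <- (state %%/%% %s) %%%% 2 == 1", i, fmt_num(2^i)
    ))
  }
  for (i in seq_len(n)) {
    nd <- network$nodes[[i]]
    lines <- c(lines, sprintf(
      "  f%d <- %s", i - 1L, codegen_expr(nd$logic)
    ))
    si <- sprintf("(state %%/%% %s) %%%% 2 == 1", fmt_num(2^(i - 1L)))
    lines <- c(lines, sprintf(
      "  r%d <- if (f%d == (%s)) 0 else if (%s) %s else %s",
      i - 1L, i - 1L, si, si,
      fmt_num(nd$rate_down), fmt_num(nd$rate_up)
    ))
  }
  lines <- c(lines, sprintf(
    "  c(%s)", paste0("r", seq_len(n) - 1L, collapse = ", ")
  ), "}")
  paste(lines, collapse = "\n")
}

codegen_expr <- function(f) {
  switch(f$op,
    var = sprintf("b%d", f$index),
    const = if (f$value == 1L) "TRUE" else "FALSE",
    not = sprintf("(!%s)", codegen_expr(f$args[[1]])),
    and = sprintf("(%s & %s)", codegen_expr(f$args[[1]]),
                  codegen_expr(f$args[[2]])),
    or = sprintf("(%s | %s)", codegen_expr(f$args[[1]]),
                 codegen_expr(f$args[[2]])),
    xor = sprintf("xor(%s, %s)", codegen_expr(f$args[[1]]),
                  codegen_expr(f$args[[2]])),
    stop("unknown formula operator: ", f$op)
  )
}

collect_indices <- function(f) {
  if (f$op == "var") return(f$index)
  if (f$op == "const") return(integer(0))
  unlist(lapply(f$args, collect_indices))
}

#' Compile a network into executable rate evaluators
#'
#' Performs the model's one-time runtime compilation: every node formula
#' is translated into (a) generated R source for a whole-network
#' rate-vector function, compiled in-process to bytecode, and (b) a
#' postfix instruction program executed by the package's C++ stack
#' machine (the path [run_simulation()] uses). Both are exact equivalents
#' of the [transition_rates()] interpreter; no formula simplification is
#' applied.
#'
#' @param network a `boolean_network` with resolved numeric rates.
#' @return a `compiled_model` with elements `network`, `evaluate`
#'   (function: state -> rate vector), `programs`, `rate_up`,
#'   `rate_down`, `istate` and `source` (the generated R code).
#' @export
compile_model <- function(network) {
  stopifnot(inherits(network, "boolean_network"))
  require_numeric_rates(network)
  if (network$n > 53) {
    stop("simulation supports at most 53 nodes (packed-state precision)")
  }
  programs <- lapply(network$nodes, function(nd) {
    tryCatch(compile_program(nd$logic), error = function(e) {
      stop("code generation failed for node '", nd$name, "': ",
           conditionMessage(e))
    })
  })
  src <- codegen_r(network)
  evaluate <- tryCatch(
    compiler::cmpfun(eval(parse(text = src), envir = baseenv())),
    error = function(e) {
      stop("rate-function code generation failed: ", conditionMessage(e))
    }
  )
  structure(
    list(
      network = network,
      evaluate = evaluate,
      source = src,
      programs = programs,
      rate_up = vapply(network$nodes, `[[`, numeric(1), "rate_up"),
      rate_down = vapply(network$nodes, `[[`, numeric(1), "rate_down"),
      istate = vapply(network$nodes, `[[`, numeric(1), "istate")
    ),
    class = "compiled_model"
  )
}

#' @export
print.compiled_model <- function(x, ...) {
  cat(
    "Compiled Boolean network:", x$network$n, "nodes,",
    sum(lengths(x$programs)) / 2, "VM instructions\n"
  )
  invisible(x)
}

# C++ bytecode path for one state; used in equivalence tests
compiled_rates_vm <- function(model, state) {
  .engine_rates(model$programs, model$rate_up, model$rate_down, state)
}
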