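# Boolean formula ASTs.
#
# A formula is a nested list with an `op` field:
#   var   - leaf, fields: name (character), index (0-based bit position,
#           resolved against the enclosing network's node order)
#   const - leaf, field: value (integer 0/1)
#   not   - field: args = list(operand)
#   and / or / xor - field: args = list(lhs, rhs)

f_var <- function(name, index = NA_integer_) {
  list(op = "var", name = name, index = as.integer(index))
}
f_const <- function(value) list(op = "const", value = as.integer(value))
f_not <- function(x) list(op = "not", args = list(x))
f_and <- function(a, b) list(op = "and", args = list(a, b))
f_or <- function(a, b) list(op = "or", args = list(a, b))
f_xor <- function(a, b) list(op = "xor", args = list(a, b))

#' Evaluate a Boolean formula on a network state
#'
#' Standard Boolean semantics over a state bitmask: bit `i` of `state`
#' holds the value of the node with index `i`. The evaluation is a pure,
#' total function of `(formula, state)`.
#'
#' @param formula a formula AST as found in `$logic` of a parsed network's
#'   nodes.
#' @param state numeric scalar; the packed state bitmask (bit `i` = value
#'   of node `i`).
#' @return integer 0 or 1.
#' @export
evaluate_formula <- function(formula, state) {
  switch(formula$op,
    var = bit_get(state, formula$index),
    const = formula$value,
    not = 1L - evaluate_formula(formula$args[[1]], state),
    and = evaluate_formula(formula$args[[1]], state) &
      evaluate_formula(formula$args[[2]], state),
    or = evaluate_formula(formula$args[[1]], state) |
      evaluate_formula(formula$args[[2]], state),
    xor = xor(
      evaluate_formula(formula$args[[1]], state),
      evaluate_formula(formula$args[[2]], state)
    ),
    stop("unknown formula operator: ", formula$op)
  ) -> v
  as.integer(v)
}

# number of operand leaves (node references and constants); the formula
# size metric is the mean leaf count over all node formulas
formula_size <- function(formula) {
  if (formula$op %in% c("var", "const")) {
    return(1L)
  }
  sum(vapply(formula$args, formula_size, integer(1)))
}

# fully parenthesized text form; re-parsing it reproduces the AST
deparse_formula <- function(formula) {
  switch(formula$op,
    var = formula$name,
    const = as.character(formula$value),
    not = paste0("!", deparse_wrap(formula$args[[1]])),
    and = paste0(
      deparse_wrap(formula$args[[1]]), " & ",
      deparse_wrap(formula$args[[2]])
    ),
    or = paste0(
      deparse_wrap(formula$args[[1]]), " | ",
      deparse_wrap(formula$args[[2]])
    ),
    xor = paste0(
      deparse_wrap(formula$args[[1]]), " ^ ",
      deparse_wrap(formula$args[[2]])
    )
  )
}

deparse_wrap <- function(formula) {
  if (formula$op %in% c("var", "const")) {
    deparse_formula(formula)
  } else {
    paste0("(", deparse_formula(formula), ")")
  }
}

# resolve leaf node names to bit indices against a name -> 0-based index map
resolve_formula <- function(formula, index_of, node_name) {
  if (formula$op == "var") {
    idx <- index_of[[formula$name]]
    if (is.null(idx)) {
      stop(
        "node '", node_name, "': logic references undeclared node '",
        formula$name, "'"
      )
    }
    formula$index <- as.integer(idx)
    return(formula)
  }
  if (formula$op == "const") {
    return(formula)
  }
  formula$args <- lapply(formula$args, resolve_formula, index_of, node_name)
  formula
}

# flatten to the postfix (opcode, arg) instruction pairs executed by the
# C++ stack machine; no simplification is performed, so program length
# tracks formula size
compile_program <- function(formula) {
  out <- integer(0)
  emit <- function(f) {
    switch(f$op,
      var = out[[length(out) + 1]] <<- c(0L, f$index),
      const = out[[length(out) + 1]] <<- c(1L, f$value),
      not = {
        emit(f$args[[1]])
        out[[length(out) + 1]] <<- c(2L, 0L)
      },
      and = {
        emit(f$args[[1]])
        emit(f$args[[2]])
        out[[length(out) + 1]] <<- c(3L, 0L)
      },
      or = {
        emit(f$args[[1]])
        emit(f$args[[2]])
        out[[length(out) + 1]] <<- c(4L, 0L)
      },
      xor = {
        emit(f$args[[1]])
        emit(f$args[[2]])
        out[[length(out) + 1]] <<- c(5L, 0L)
      },
      stop("unknown formula operator: ", f$op)
    )
  }
  out <- vector("list", 0)
  emit(formula)
  as.integer(unlist(out))
}

# ---- bit helpers on double-packed states (exact for n <= 53) ----

bit_get <- function(state, i) as.integer((state %/% 2^i) %% 2)

bit_flip <- function(state, i) {
  state + (1 - 2 * bit_get(state, i)) * 2^i
}

state_from_bits <- function(bits) {
  sum(as.numeric(bits) * 2^(seq_along(bits) - 1))
}

state_to_bits <- function(state, n) {
  vapply(seq_len(n) - 1L, function(i) bit_get(state, i), integer(1))
}
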