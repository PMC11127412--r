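# Parsing of the .bnd network / .cfg configuration dialect.
#
# .bnd:  node <name> { logic = <expr>; [rate_up = <num|$param>;]
#                      [rate_down = <num|$param>;] }   (repeated)
# .cfg:  $<param> = <num>;
#        <node>.is_internal = TRUE|FALSE;  <node>.istate = <num>;
#        <node>.rate_up / rate_down = <num|$param>;
#        max_time / time_tick / sample_count / seed / workers /
#        max_steps = <num>;
# `//` starts a comment; statements end with `;`.
#
# Operator precedence in logic expressions: NOT > AND > XOR > OR.
# `&`/`AND`, `|`/`OR`, `!`/`NOT`, `^`/`XOR` are interchangeable
# (keywords case-insensitive); literals 0/1; parentheses.

# ---- tokenizer -------------------------------------------------------

token_regexes <- c(
  ws = "[ \t\r\n]+",
  comment = "//[^\n]*",
  number = "[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?",
  param = "\\$[A-Za-z_][A-Za-z0-9_]*",
  ident = "[A-Za-z_][A-Za-z0-9_]*",
  sym = "[{}();=.&|!^]"
)

tokenize <- function(text) {
  pos <- 1L
  nc <- nchar(text)
  toks <- list()
  line <- 1L
  col <- 1L
  while (pos <= nc) {
    rest <- substr(text, pos, nc)
    matched <- FALSE
    for (kind in names(token_regexes)) {
      m <- regmatches(rest, regexpr(
        paste0("^(", token_regexes[[kind]], ")"), rest
      ))
      if (length(m) == 1) {
        if (!kind %in% c("ws", "comment")) {
          toks[[length(toks) + 1]] <- list(
            kind = kind, text = m, line = line, col = col
          )
        }
        nl <- lengths(regmatches(m, gregexpr("\n", m, fixed = TRUE)))
        if (nl > 0) {
          line <- line + nl
          col <- nchar(sub(".*\n", "", m)) + 1L
        } else {
          col <- col + nchar(m)
        }
        pos <- pos + nchar(m)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf(
        "syntax error at line %d, column %d: unexpected character '%s'",
        line, col, substr(text, pos, pos)
      ))
    }
  }
  toks
}

# cursor over a token list with one-token lookahead
token_cursor <- function(toks) {
  i <- 0L
  peek <- function() if (i < length(toks)) toks[[i + 1L]] else NULL
  advance <- function() {
    i <<- i + 1L
    toks[[i]]
  }
  expect <- function(text = NULL, kind = NULL) {
    tk <- peek()
    if (is.null(tk)) stop("syntax error: unexpected end of input")
    if (!is.null(text) && !identical(tk$text, text)) {
      stop(sprintf(
        "syntax error at line %d, column %d: expected '%s', found '%s'",
        tk$line, tk$col, text, tk$text
      ))
    }
    if (!is.null(kind) && !identical(tk$kind, kind)) {
      stop(sprintf(
        "syntax error at line %d, column %d: expected %s, found '%s'",
        tk$line, tk$col, kind, tk$text
      ))
    }
    advance()
  }
  list(peek = peek, advance = advance, expect = expect)
}

is_keyword <- function(tk, word) {
  !is.null(tk) && tk$kind == "ident" && toupper(tk$text) == word
}

# ---- logic expression parser (recursive descent) ---------------------

parse_expr <- function(cur) parse_or(cur)

parse_or <- function(cur) {
  lhs <- parse_xor(cur)
  repeat {
    tk <- cur$peek()
    if (!is.null(tk) && (tk$text == "|" || is_keyword(tk, "OR"))) {
      cur$advance()
      lhs <- f_or(lhs, parse_xor(cur))
    } else {
      return(lhs)
    }
  }
}

parse_xor <- function(cur) {
  lhs <- parse_and(cur)
  repeat {
    tk <- cur$peek()
    if (!is.null(tk) && (tk$text == "^" || is_keyword(tk, "XOR"))) {
      cur$advance()
      lhs <- f_xor(lhs, parse_and(cur))
    } else {
      return(lhs)
    }
  }
}

parse_and <- function(cur) {
  lhs <- parse_unary(cur)
  repeat {
    tk <- cur$peek()
    if (!is.null(tk) && (tk$text == "&" || is_keyword(tk, "AND"))) {
      cur$advance()
      lhs <- f_and(lhs, parse_unary(cur))
    } else {
      return(lhs)
    }
  }
}

parse_unary <- function(cur) {
  tk <- cur$peek()
  if (!is.null(tk) && (tk$text == "!" || is_keyword(tk, "NOT"))) {
    cur$advance()
    return(f_not(parse_unary(cur)))
  }
  parse_primary(cur)
}

parse_primary <- function(cur) {
  tk <- cur$peek()
  if (is.null(tk)) stop("syntax error: unexpected end of logic expression")
  if (tk$text == "(") {
    cur$advance()
    e <- parse_expr(cur)
    cur$expect(")")
    return(e)
  }
  if (tk$kind == "number") {
    cur$advance()
    if (!tk$text %in% c("0", "1")) {
      stop(sprintf(
        "syntax error at line %d, column %d: only literals 0/1 allowed",
        tk$line, tk$col
      ))
    }
    return(f_const(as.integer(tk$text)))
  }
  if (tk$kind == "ident") {
    cur$advance()
    return(f_var(tk$text))
  }
  stop(sprintf(
    "syntax error at line %d, column %d: unexpected '%s' in expression",
    tk$line, tk$col, tk$text
  ))
}

# ---- .bnd ------------------------------------------------------------

#' Parse a .bnd Boolean network file
#'
#' Reads the network dialect: one `node <name> { ... }` block per node,
#' each holding a `logic` formula and optional `rate_up` / `rate_down`
#' clauses (numbers or `$param` references resolved later by
#' [parse_cfg()]). Node order in the file fixes the bit positions of the
#' packed state representation. Missing rates default to 1, the initial
#' activation probability defaults to 0.5 and nodes start non-internal;
#' a configuration file can override all three.
#'
#' @param text the file contents as a single string, or a character
#'   vector of lines.
#' @return a `boolean_network` object.
#' @seealso [parse_cfg()], [write_bnd()], [read_model()]
#' @export
parse_bnd <- function(text) {
  text <- paste(text, collapse = "\n")
  cur <- token_cursor(tokenize(text))
  nodes <- list()
  while (!is.null(cur$peek())) {
    tk <- cur$peek()
    if (!is_keyword(tk, "NODE")) {
      stop(sprintf(
        "syntax error at line %d, column %d: expected 'node', found '%s'",
        tk$line, tk$col, tk$text
      ))
    }
    cur$advance()
    name_tk <- cur$expect(kind = "ident")
    name <- name_tk$text
    if (name %in% vapply(nodes, `[[`, "", "name")) {
      stop("duplicate node name '", name, "'")
    }
    cur$expect("{")
    spec <- list(
      name = name, logic = NULL, rate_up = 1, rate_down = 1,
      is_internal = FALSE, istate = 0.5
    )
    while (!identical(cur$peek()$text, "}")) {
      key_tk <- cur$expect(kind = "ident")
      key <- key_tk$text
      cur$expect("=")
      if (key == "logic") {
        spec$logic <- parse_expr(cur)
      } else if (key %in% c("rate_up", "rate_down")) {
        vtk <- cur$advance()
        if (vtk$kind == "number") {
          spec[[key]] <- as.numeric(vtk$text)
        } else if (vtk$kind == "param") {
          spec[[key]] <- vtk$text
        } else {
          stop(sprintf(
            "syntax error at line %d, column %d: bad rate value '%s'",
            vtk$line, vtk$col, vtk$text
          ))
        }
      } else {
        stop(sprintf(
          "syntax error at line %d, column %d: unknown node key '%s'",
          key_tk$line, key_tk$col, key
        ))
      }
      cur$expect(";")
    }
    cur$expect("}")
    if (is.null(spec$logic)) {
      stop("node '", name, "' has no logic formula")
    }
    nodes[[length(nodes) + 1]] <- spec
  }
  boolean_network(nodes)
}

#' Construct a Boolean network from node specifications
#'
#' Nodes are ordered: the i-th node occupies bit i-1 of the packed state.
#' Logic formulas may reference any declared node by name; references are
#' resolved here and undeclared names are an error.
#'
#' @param nodes list of node specifications, each a list with fields
#'   `name`, `logic` (formula AST), and optionally `rate_up`, `rate_down`
#'   (positive numbers or `"$param"` strings), `is_internal`, `istate`.
#' @param params named numeric vector of `$param` values.
#' @return a `boolean_network` object.
#' @export
boolean_network <- function(nodes, params = numeric(0)) {
  names_ <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(names_)) {
    stop("duplicate node name '", names_[duplicated(names_)][1], "'")
  }
  index_of <- as.list(setNames(seq_along(names_) - 1L, names_))
  defaults <- list(rate_up = 1, rate_down = 1, is_internal = FALSE,
                   istate = 0.5)
  nodes <- lapply(nodes, function(nd) {
    nd <- modifyList(defaults, nd[!vapply(nd, is.null, TRUE)])
    nd$logic <- resolve_formula(nd$logic, index_of, nd$name)
    validate_node(nd)
    nd[c("name", "logic", "rate_up", "rate_down", "is_internal", "istate")]
  })
  structure(
    list(nodes = nodes, n = length(nodes), params = params),
    class = "boolean_network"
  )
}

validate_node <- function(nd) {
  for (key in c("rate_up", "rate_down")) {
    v <- nd[[key]]
    if (is.numeric(v)) {
      if (!is.finite(v) || v <= 0) {
        stop("node '", nd$name, "': ", key, " must be positive")
      }
    } else if (!(is.character(v) && grepl("^\\$", v))) {
      stop("node '", nd$name, "': ", key, " must be a number or $param")
    }
  }
  if (!is.numeric(nd$istate) || nd$istate < 0 || nd$istate > 1) {
    stop("node '", nd$name, "': istate must lie in [0, 1]")
  }
  invisible(nd)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network:", x$n, "nodes\n")
  for (nd in x$nodes) {
    cat(sprintf(
      "  %s%s: logic = %s; up = %s, down = %s, istate = %g\n",
      nd$name, if (nd$is_internal) " [internal]" else "",
      deparse_formula(nd$logic),
      format(nd$rate_up), format(nd$rate_down), nd$istate
    ))
  }
  if (length(x$params)) {
    cat("  parameters:", paste(names(x$params), "=", x$params,
                               collapse = ", "), "\n")
  }
  invisible(x)
}

node_names <- function(network) {
  vapply(network$nodes, `[[`, "", "name")
}

# ---- .cfg ------------------------------------------------------------

#' Parse a .cfg simulation configuration against a parsed network
#'
#' Resolves `$param` definitions into node rates, applies per-node
#' `is_internal` / `istate` / rate overrides, and collects the simulation
#' keys into a [simulation_config()]. `max_time` is required; defaults:
#' `time_tick` 0.1, `sample_count` 10000, `seed` 0, `workers` 1,
#' `max_steps` unbounded.
#'
#' @param text configuration file contents (string or lines).
#' @param network a `boolean_network` from [parse_bnd()].
#' @return list with elements `network` (rates resolved, flags applied)
#'   and `config` (a `simulation_config`).
#' @export
parse_cfg <- function(text, network) {
  stopifnot(inherits(network, "boolean_network"))
  text <- paste(text, collapse = "\n")
  cur <- token_cursor(tokenize(text))
  params <- as.list(network$params)
  sim <- list()
  names_ <- node_names(network)
  nodes <- network$nodes
  sim_keys <- c(
    "max_time", "time_tick", "sample_count", "seed", "workers", "max_steps"
  )
  while (!is.null(cur$peek())) {
    tk <- cur$advance()
    if (tk$kind == "param") {
      cur$expect("=")
      vtk <- cur$expect(kind = "number")
      params[[substring(tk$text, 2)]] <- as.numeric(vtk$text)
      cur$expect(";")
    } else if (tk$kind == "ident" && tk$text %in% sim_keys) {
      cur$expect("=")
      vtk <- cur$expect(kind = "number")
      sim[[tk$text]] <- as.numeric(vtk$text)
      cur$expect(";")
    } else if (tk$kind == "ident" && tk$text %in% names_) {
      i <- match(tk$text, names_)
      cur$expect(".")
      key_tk <- cur$expect(kind = "ident")
      key <- key_tk$text
      cur$expect("=")
      vtk <- cur$advance()
      if (key == "is_internal") {
        if (!(vtk$kind == "ident" && toupper(vtk$text) %in% c("TRUE", "FALSE"))) {
          stop(sprintf(
            "line %d: is_internal must be TRUE or FALSE", vtk$line
          ))
        }
        nodes[[i]]$is_internal <- toupper(vtk$text) == "TRUE"
      } else if (key == "istate") {
        if (vtk$kind != "number") {
          stop(sprintf("line %d: istate must be a number", vtk$line))
        }
        v <- as.numeric(vtk$text)
        if (v < 0 || v > 1) {
          stop("istate for node '", tk$text, "' outside [0, 1]: ", v)
        }
        nodes[[i]]$istate <- v
      } else if (key %in% c("rate_up", "rate_down")) {
        if (vtk$kind == "number") {
          nodes[[i]][[key]] <- as.numeric(vtk$text)
        } else if (vtk$kind == "param") {
          nodes[[i]][[key]] <- vtk$text
        } else {
          stop(sprintf("line %d: bad rate value '%s'", vtk$line, vtk$text))
        }
      } else {
        stop(sprintf(
          "line %d: unknown node key '%s' for node '%s'",
          key_tk$line, key, tk$text
        ))
      }
      cur$expect(";")
    } else {
      stop(sprintf(
        "line %d: unknown configuration key '%s'", tk$line, tk$text
      ))
    }
  }
  # substitute $params into rates
  nodes <- lapply(nodes, function(nd) {
    for (key in c("rate_up", "rate_down")) {
      v <- nd[[key]]
      if (is.character(v)) {
        pname <- substring(v, 2)
        if (is.null(params[[pname]])) {
          stop("node '", nd$name, "': unresolved parameter ", v)
        }
        nd[[key]] <- params[[pname]]
      }
      if (nd[[key]] <= 0) {
        stop("node '", nd$name, "': non-positive ", key,
             " after parameter resolution")
      }
    }
    nd
  })
  network$nodes <- nodes
  network$params <- unlist(params) %||% numeric(0)
  if (is.null(sim$max_time)) stop("configuration must set max_time")
  config <- do.call(simulation_config, sim)
  list(network = network, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' @param max_time positive real; trajectories run on `[0, max_time]`.
#' @param time_tick positive real; width of the statistics windows
#'   (0.1 by default, matching the usual window width).
#' @param sample_count number of trajectories to simulate.
#' @param seed non-negative integer master seed; every trajectory derives
#'   its own reproducible substream from `(seed, trajectory index)`.
#' @param workers positive integer; the number of logical workers the
#'   trajectory set is partitioned over. Results are bit-identical for
#'   every value.
#' @param max_steps optional cap on transitions per trajectory
#'   (`Inf` = unbounded).
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(max_time, time_tick = 0.1,
                              sample_count = 10000, seed = 0,
                              workers = 1, max_steps = Inf) {
  stopifnot(
    is.numeric(max_time), max_time > 0,
    is.numeric(time_tick), time_tick > 0, time_tick <= max_time,
    sample_count >= 1, seed >= 0, workers >= 1,
    max_steps > 0
  )
  structure(
    list(
      max_time = max_time, time_tick = time_tick,
      sample_count = as.numeric(round(sample_count)),
      seed = as.numeric(round(seed)),
      workers = as.integer(workers),
      max_steps = if (is.finite(max_steps)) as.numeric(round(max_steps)) else Inf
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    paste0("Simulation config: max_time = %g, time_tick = %g, ",
           "sample_count = %g, seed = %g, workers = %d, max_steps = %s\n"),
    x$max_time, x$time_tick, x$sample_count, x$seed, x$workers,
    if (is.finite(x$max_steps)) format(x$max_steps) else "unbounded"
  ))
  invisible(x)
}

# ---- writers ---------------------------------------------------------

fmt_num <- function(x) {
  # shortest representation that survives a parse round-trip
  for (digits in 1:17) {
    s <- sprintf(paste0("%.", digits, "g"), x)
    if (as.numeric(s) == x) return(s)
  }
  s
}

fmt_rate <- function(v) if (is.character(v)) v else fmt_num(v)

#' Serialize a network to .bnd text
#'
#' The output re-parses to a structurally identical network (same node
#' order, formula ASTs and rates; `$param` rates are preserved
#' symbolically).
#'
#' @param network a `boolean_network`.
#' @return a single string of .bnd text.
#' @export
write_bnd <- function(network) {
  blocks <- vapply(network$nodes, function(nd) {
    paste0(
      "node ", nd$name, " {\n",
      "  logic = ", deparse_formula(nd$logic), ";\n",
      "  rate_up = ", fmt_rate(nd$rate_up), ";\n",
      "  rate_down = ", fmt_rate(nd$rate_down), ";\n",
      "}\n"
    )
  }, "")
  paste(blocks, collapse = "\n")
}

#' Serialize configuration (+ per-node flags) to .cfg text
#'
#' @param network a `boolean_network` (its `$param` table, internal flags
#'   and initial-state probabilities are emitted here).
#' @param config a `simulation_config`.
#' @return a single string of .cfg text.
#' @export
write_cfg <- function(network, config) {
  lines <- character(0)
  if (length(network$params)) {
    lines <- c(lines, sprintf(
      "$%s = %s;", names(network$params), vapply(network$params, fmt_num, "")
    ))
  }
  for (nd in network$nodes) {
    lines <- c(
      lines,
      sprintf("%s.is_internal = %s;", nd$name,
              if (nd$is_internal) "TRUE" else "FALSE"),
      sprintf("%s.istate = %s;", nd$name, fmt_num(nd$istate))
    )
  }
  lines <- c(
    lines,
    sprintf("max_time = %s;", fmt_num(config$max_time)),
    sprintf("time_tick = %s;", fmt_num(config$time_tick)),
    sprintf("sample_count = %s;", fmt_num(config$sample_count)),
    sprintf("seed = %s;", fmt_num(config$seed)),
    sprintf("workers = %d;", config$workers)
  )
  if (is.finite(config$max_steps)) {
    lines <- c(lines, sprintf("max_steps = %s;", fmt_num(config$max_steps)))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read a model from .bnd and .cfg files
#'
#' @param bnd_path path to the network file.
#' @param cfg_path path to the configuration file.
#' @return list with `network` and `config`, as from [parse_cfg()].
#' @export
read_model <- function(bnd_path, cfg_path) {
  network <- parse_bnd(readLines(bnd_path, warn = FALSE))
  parse_cfg(readLines(cfg_path, warn = FALSE), network)
}
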