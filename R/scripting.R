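# Embedded scripts.  `scriptdef { ... }` blocks accumulate host-language
# (R) definitions into a script environment (a string, concatenated in scope
# order); `script { ... }` blocks evaluate, under that environment, to a
# string which must itself be a program with a hole at its end; the
# continuation of the block is spliced into the hole and compilation
# recurses.  Scripts run in a restricted evaluation environment exposing
# only string and sequence helpers: no filesystem, network or package
# access, so compilation stays deterministic.

lbsk_script_error <- function(msg) {
  stop(errorCondition(paste0("script error: ", msg),
                      class = c("lbsk_script_error", "lbsk_error")))
}

script_whitelist <- c(
  "paste", "paste0", "sprintf", "format", "formatC", "strrep", "substr",
  "substring", "nchar", "toupper", "tolower", "trimws", "strsplit", "gsub",
  "sub", "grepl", "startsWith", "endsWith", "rev", "sort", "unique", "head",
  "tail", "seq", "seq_len", "seq_along", "rep", "c", "unlist", "list",
  "vapply", "sapply", "lapply", "mapply", "Map", "Reduce", "Filter", "do.call",
  "length", "sum", "prod", "cumsum", "max", "min", "abs", "floor", "ceiling",
  "round", "as.character", "as.integer", "as.numeric", "is.character",
  "is.numeric", "nchar", "setdiff", "union", "intersect", "match", "which",
  "ifelse", "identical", "stop", "stopifnot",
  "+", "-", "*", "/", "%%", "%/%", "^", ":", "==", "!=", "<", ">", "<=",
  ">=", "&", "|", "&&", "||", "!", "(", "{", "[", "[[", "<-", "<<-", "=",
  "if", "for", "while", "repeat", "break", "next", "function", "return",
  "invisible", "missing", "is.null", "Recall"
)

make_script_env <- function() {
  env <- new.env(parent = emptyenv())
  for (nm in script_whitelist) {
    fn <- tryCatch(get(nm, envir = baseenv()), error = function(e) NULL)
    if (!is.null(fn)) assign(nm, fn, envir = env)
  }
  env
}

#' Evaluate an embedded script block
#'
#' The accumulated script definitions and the block's code are evaluated in
#' a sandboxed R environment; the value of the last expression must be a
#' character vector, which is returned joined with newlines as program text
#' (to be parsed and spliced by the compiler).
#'
#' @param code Script source (R).
#' @param env Script environment: the accumulated `scriptdef` text.
#' @return The program text produced by the script.
#' @export
run_script <- function(code, env = "") {
  full <- paste(env, code, sep = "\n")
  exprs <- tryCatch(parse(text = full),
                    error = function(e) {
                      lbsk_script_error(paste0("script does not parse: ",
                                               conditionMessage(e)))
                    })
  sandbox <- make_script_env()
  val <- NULL
  for (e in exprs) {
    val <- tryCatch(eval(e, sandbox),
                    error = function(err) {
                      lbsk_script_error(conditionMessage(err))
                    })
  }
  if (!is.character(val)) {
    lbsk_script_error("a script block must evaluate to a character string")
  }
  paste(val, collapse = "\n")
}

#' Accumulate a scriptdef block into the script environment
#'
#' The block must contain only definitions (top-level assignments); its text
#' is appended to the environment.
#'
#' @inheritParams run_script
#' @return The extended script environment (a string).
#' @export
collect_scriptdef <- function(code, env = "") {
  exprs <- tryCatch(parse(text = code),
                    error = function(e) {
                      lbsk_script_error(paste0("scriptdef does not parse: ",
                                               conditionMessage(e)))
                    })
  for (e in exprs) {
    if (!(is.call(e) && as.character(e[[1L]]) %in% c("<-", "=", "assign"))) {
      lbsk_script_error("a scriptdef block may only contain definitions")
    }
  }
  if (!nzchar(trimws(code))) return(env)
  paste0(env, if (nzchar(env)) "\n" else "", code)
}
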