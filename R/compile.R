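# Front-end pipeline: source text -> parse -> desugar -> elaborate ->
# Kappa translation.

#' Compile an LBS-kappa model to a flat Kappa program
#'
#' Runs the full pipeline: parsing, desugaring, elaboration to normal-form
#' rules and initial populations, and translation to flat Kappa with
#' per-rule link encoding, compartment-encoding `comp` sites and
#' well-typedness checking.
#'
#' @param text Model source text (character; joined with newlines).
#' @param file Path to a `.lbsk` file (alternative to `text`).
#' @param allow_scripts Evaluate embedded `script`/`scriptdef` blocks?
#'   Off by default.
#' @return An object of class `kappa_program` with `rules`, `inits` and
#'   `%agent:` `signatures`; the elaboration result is attached as
#'   attribute `ir`.
#' @examples
#' k <- lbsk_compile("
#'   agent A = new {x};
#'   agent B = new {y};
#'   A{x} + B{y} -> {0.1} A{x!1}-B{y!1}")
#' length(k$rules)
#' @export
lbsk_compile <- function(text = NULL, file = NULL, allow_scripts = FALSE) {
  if (is.null(text)) {
    if (is.null(file)) stop("either 'text' or 'file' must be given")
    text <- readLines(file, warn = FALSE)
  }
  ast <- lbsk_desugar(lbsk_parse(text))
  ir <- lbsk_elaborate(ast, allow_scripts = allow_scripts)
  k <- ir_to_kappa(ir)
  attr(k, "ir") <- ir
  k
}

ir_to_kappa <- function(ir) {
  name_map <- printable_names(ir$agents)
  rules <- lapply(ir$rules, rule_to_kappa, name_map = name_map)
  inits <- lapply(ir$inits, init_to_kappa, name_map = name_map)

  # %agent signatures: declared internal values per site, plus the comp
  # site listing every compartment token this agent kind is used at
  tokens <- list()
  note_tokens <- function(agents) {
    for (a in agents) {
      for (s in a$sites) {
        if (s$name == "comp") {
          tokens[[a$name]] <<- union(tokens[[a$name]], s$internal)
        }
      }
    }
  }
  for (r in rules) {
    note_tokens(r$lhs)
    note_tokens(r$rhs)
  }
  for (ini in inits) note_tokens(ini$agents)

  signatures <- list()
  for (uid in names(ir$agents)) {
    reg <- ir$agents[[uid]]
    nm <- name_map[[uid]]
    sig <- reg$sig
    sig[["comp"]] <- tokens[[nm]] %||% "top"
    signatures[[nm]] <- sig
  }
  kappa_program(rules, inits, signatures)
}
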