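# Abstract syntax nodes.  Nodes are plain lists tagged with $kind so that two
# parses of the same text are `identical()`; source positions live only in
# error messages raised during parsing.

node <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "lbsk_node")
}

# --- program nodes -----------------------------------------------------------

ast_nil <- function() node("nil")
ast_parallel <- function(left, right) node("parallel", left = left, right = right)
ast_located <- function(comp, body) node("located", comp = comp, body = body)
ast_scoped <- function(def, body) node("scoped", def = def, body = body)
# lhs/rhs: lists of terms; a term is list(expr = <agent expr>, as = chr | NULL)
ast_rule <- function(lhs, rhs, fwd = NULL, rev = NULL, reversible = FALSE) {
  node("rule", lhs = lhs, rhs = rhs, fwd = fwd, rev = rev,
       reversible = reversible)
}
ast_invoke <- function(module, actuals) node("invoke", module = module,
                                             actuals = actuals)
ast_init <- function(expr, count) node("init", expr = expr, count = count)
ast_script <- function(code, body) node("script", code = code, body = body)
ast_scriptdef <- function(code, body) node("scriptdef", code = code, body = body)

# --- definitions -------------------------------------------------------------

ast_agent_def <- function(ids, expr) node("agent_def", ids = ids, expr = expr)
ast_comp_def <- function(id, parent = NULL) node("comp_def", id = id,
                                                 parent = parent)
ast_rate_def <- function(id, expr) node("rate_def", id = id, expr = expr)
# formals: list(comps = chr vector, agents = list of list(id, ann), rates = chr)
ast_module_def <- function(id, formals, body) node("module_def", id = id,
                                                   formals = formals,
                                                   body = body)

# --- agent expressions -------------------------------------------------------

# sig: named list site name -> character vector of internal state values
ast_new_agent <- function(name, sig) node("new_agent", name = name, sig = sig)
ast_ident <- function(id) node("ident", id = id)
# literal Id{...}: sugar for Id<Id{...}> (resolved in desugar)
ast_literal <- function(id, sites) node("literal", id = id, sites = sites)
ast_update <- function(base, target, sites) node("update", base = base,
                                                 target = target, sites = sites)
ast_compose <- function(left, right) node("compose", left = left, right = right)
ast_choice <- function(left, right) node("choice", left = left, right = right)
ast_loc_expr <- function(comp, body) node("loc_expr", comp = comp, body = body)

# --- site expressions (syntax level) ----------------------------------------
# internal: NULL (omitted) | list(kind = "value", v) | list(kind = "wildcard")
#           | list(kind = "identity")
# link: NULL (omitted) | list(kind = "free" | "bound" | "any" | "identity")
#       | list(kind = "label", k = int)   (namespace attached at elaboration)

site_entry <- function(name, internal = NULL, link = NULL) {
  list(name = name, internal = internal, link = link)
}

int_value <- function(v) list(kind = "value", v = v)
int_wildcard <- function() list(kind = "wildcard")
int_identity <- function() list(kind = "identity")
link_free <- function() list(kind = "free")
link_bound <- function() list(kind = "bound")       # !_  bound to something
link_any <- function() list(kind = "any")           # ?   free or bound
link_identity <- function() list(kind = "identity") # !e
link_label <- function(k, ns = "") list(kind = "label", k = k, ns = ns)

# --- rate expressions --------------------------------------------------------

rate_const <- function(value) node("rate_const", value = value)
rate_ident <- function(id) node("rate_ident", id = id)
rate_binop <- function(op, left, right) node("rate_binop", op = op,
                                             left = left, right = right)

# --- actual module parameters ------------------------------------------------

actual_agent <- function(expr, ann) list(kind = "agent_actual", expr = expr,
                                         ann = ann)
actual_rate <- function(expr) list(kind = "rate_actual", expr = expr)
# a bare identifier: agent, rate or compartment depending on the formal
actual_ident <- function(id) list(kind = "ident_actual", id = id)

# annotation: list of items, item = list(name = chr | NULL,
#   sites = list of list(name = chr, type = chr vector | NULL))
ann_item <- function(name, sites) list(name = name, sites = sites)

#' @export
print.lbsk_node <- function(x, ...) {
  cat("<lbsk ast:", x$kind, "node>\n")
  cat(lbsk_format(x), "\n")
  invisible(x)
}

ast_walk <- function(x, fn) {
  # Pre-order traversal over every lbsk_node reachable from x.
  if (inherits(x, "lbsk_node")) fn(x)
  if (is.list(x)) {
    for (el in x) {
      if (is.list(el)) ast_walk(el, fn)
    }
  }
  invisible(NULL)
}

ast_count <- function(x, kind) {
  k <- 0L
  ast_walk(x, function(nd) if (nd$kind %in% kind) k <<- k + 1L)
  k
}
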