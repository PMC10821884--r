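# Independent oracles for the FBA engine. Both are deliberately naive and
# share no code with the package's simplex:
#  * brute_force_fba enumerates candidate vertices of {S v = 0, lb<=v<=ub}
#    (free-column subsets solved against all bound assignments of the rest)
#    and picks the best feasible objective;
#  * cobra_objectives batch-solves SBML files with the cobrapy/GLPK stack.

brute_force_fba <- function(obj, S, lb, ub, tol = 1e-7) {
  n <- length(obj)
  r <- qr(S)$rank
  best <- -Inf
  for (k in 0:r) {
    sets <- if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
    for (Fset in sets) {
      Nset <- setdiff(seq_len(n), Fset)
      if (length(Nset)) {
        grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(Nset))))
        VN <- matrix(ifelse(t(grid), ub[Nset], lb[Nset]), nrow = length(Nset))
      } else VN <- matrix(numeric(0), 0, 1)
      RHS <- -S[, Nset, drop = FALSE] %*% VN
      VF <- if (k > 0)
        tryCatch(qr.solve(qr(S[, Fset, drop = FALSE]), RHS),
                 error = function(e) NULL)
      else matrix(numeric(0), 0, ncol(RHS))
      if (is.null(VF)) next
      if (k == 1) VF <- matrix(VF, nrow = 1)
      for (j in seq_len(ncol(RHS))) {
        v <- numeric(n)
        v[Nset] <- VN[, j]
        if (k) v[Fset] <- VF[, j]
        if (max(abs(S %*% v)) > tol) next
        if (any(v < lb - tol) || any(v > ub + tol)) next
        val <- sum(obj * v)
        if (val > best) best <- val
      }
    }
  }
  list(feasible = is.finite(best), value = if (is.finite(best)) best else NA_real_)
}

# Solve many SBML files with cobrapy in one python invocation; returns a
# data.frame(status, value) aligned with `paths`.
cobra_objectives <- function(paths) {
  listing <- tempfile(fileext = ".txt")
  out <- tempfile(fileext = ".json")
  writeLines(paths, listing)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import cobra",
    "from cobra.io import read_sbml_model",
    "paths = [l.strip() for l in open(sys.argv[1]) if l.strip()]",
    "res = []",
    "for p in paths:",
    "    m = read_sbml_model(p)",
    "    sol = m.optimize()",
    "    res.append({'status': sol.status, 'value': None if sol.objective_value is None else float(sol.objective_value)})",
    "json.dump(res, open(sys.argv[2], 'w'))"), script)
  status <- system2("python", c(script, listing, out), stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(out))
    stop("cobrapy oracle run failed")
  res <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  data.frame(
    status = vapply(res, function(r) r$status, ""),
    value = vapply(res, function(r) r$value %||% NA_real_, numeric(1)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
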