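#' Construct an empty solvation parameter table
#'
#' The table holds, for each of the 40 bead types and each environment
#' (water, cyclohexane), the four tunable solvation parameters: the
#' solvation volume V (A^3), the correlation length lambda (A), the
#' reference solvation free energy dGref (kcal/mol) and the free-group
#' solvation free energy dGfree (kcal/mol); plus the fixed bead radius R
#' (A).  That is 40 x 2 x 4 = 320 tunable slots.
#'
#' @return object of class `cg_parameter_table`: a list with `types` and
#'   data.frames `water` and `chex`
#' @export
parameter_table_template <- function() {
  reg <- bead_type_registry()
  env_df <- data.frame(type = reg$name, V = NA_real_, lambda = NA_real_,
                       dgref = NA_real_, dgfree = NA_real_, R = NA_real_,
                       stringsAsFactors = FALSE)
  rownames(env_df) <- reg$name
  structure(list(types = reg$name, water = env_df, chex = env_df),
            class = "cg_parameter_table")
}

#' @export
print.cg_parameter_table <- function(x, ...) {
  nslot <- length(x$types) * 2 * 4
  cat("Solvation parameter table:", length(x$types), "bead types x 2",
      "environments x 4 parameters =", nslot, "slots\n")
  cat("  water dGref range: [",
      round(min(x$water$dgref), 2), ",", round(max(x$water$dgref), 2), "]\n")
  invisible(x)
}

#' Number of tunable slots in a parameter table
#' @param table a `cg_parameter_table`
#' @return integer, types x environments x parameters
#' @export
n_parameter_slots <- function(table) length(table$types) * 2L * 4L

.tunable_params <- c("V", "lambda", "dgref", "dgfree")

#' Seed the bead parameter table from united-atom parameters
#'
#' Initial bead values are built from the atomic table: V, dGref and dGfree
#' of a bead are sums over its constituent atoms; lambda is the
#' volume-weighted mean of the constituent lambdas (a correlation length is
#' not additive); R is the radius of the sphere whose volume equals the sum
#' of the constituent van der Waals sphere volumes.  A bead type appearing
#' in several residues gets the mean over its occurrences; types not used
#' by the mapping are filled with the mean over their polarity class (or
#' the global mean as a last resort) so that every one of the 320 slots is
#' populated.
#'
#' @param atomic united-atom table, default [atomic_solvation_table()]
#' @param mapping residue mapping, default [residue_mapping()]
#' @return a fully populated `cg_parameter_table`
#' @export
init_from_atomic <- function(atomic = atomic_solvation_table(),
                             mapping = residue_mapping()) {
  tab <- parameter_table_template()
  reg <- bead_type_registry()
  acc <- list() # per type: list of instance parameter rows per env
  for (res in names(mapping)) {
    for (bead in mapping[[res]]) {
      ua <- bead$atoms$ua_type
      miss <- setdiff(ua, atomic$type)
      if (length(miss))
        stop("united-atom type(s) not in atomic table: ",
             paste(miss, collapse = ", "))
      a <- atomic[ua, , drop = FALSE]
      V <- sum(a$volume)
      lam <- sum(a$lambda * a$volume) / V
      R <- sum(a$rvdw^3)^(1 / 3)
      inst <- data.frame(
        V = V, lambda = lam, R = R,
        dgref_w = sum(a$dgref_w), dgfree_w = sum(a$dgfree_w),
        dgref_c = sum(a$dgref_c), dgfree_c = sum(a$dgfree_c))
      acc[[bead$type]] <- c(acc[[bead$type]], list(inst))
    }
  }
  filled <- names(acc)
  put <- function(tab, type, row) {
    tab$water[type, c("V", "lambda", "dgref", "dgfree", "R")] <-
      c(row$V, row$lambda, row$dgref_w, row$dgfree_w, row$R)
    tab$chex[type, c("V", "lambda", "dgref", "dgfree", "R")] <-
      c(row$V, row$lambda, row$dgref_c, row$dgfree_c, row$R)
    tab
  }
  means <- list()
  for (ty in filled) {
    m <- as.data.frame(lapply(do.call(rbind, acc[[ty]]), mean))
    means[[ty]] <- m
    tab <- put(tab, ty, m)
  }
  # unfilled types: polarity-class mean, then global mean
  all_means <- do.call(rbind, means)
  for (ty in setdiff(tab$types, filled)) {
    cls <- reg$class[match(ty, reg$name)]
    same <- filled[reg$class[match(filled, reg$name)] == cls]
    m <- if (length(same)) {
      as.data.frame(lapply(do.call(rbind, means[same]), mean))
    } else {
      as.data.frame(lapply(all_means, mean))
    }
    tab <- put(tab, ty, m)
  }
  tab
}

#' Write / read a parameter table as YAML
#' @param table a `cg_parameter_table`
#' @param path file path
#' @return `write_table`: path invisibly; `read_table`: the table
#' @export
write_table <- function(table, path) {
  out <- list(environments = list())
  for (env in c("water", "chex")) {
    df <- table[[env]]
    out$environments[[env]] <- lapply(seq_len(nrow(df)), function(r) {
      # full-precision strings: YAML double emission truncates digits
      lapply(as.list(df[r, c("V", "lambda", "dgref", "dgfree", "R")]),
             function(v) format(v, digits = 17))
    })
    names(out$environments[[env]]) <- df$type
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$environments))
    stop("schema violation: top-level 'environments' key missing")
  tab <- parameter_table_template()
  for (env in c("water", "chex")) {
    block <- raw$environments[[env]]
    if (is.null(block))
      stop("schema violation: environment '", env, "' missing")
    extra <- setdiff(names(block), tab$types)
    if (length(extra))
      warning("ignoring unknown bead type(s): ", paste(extra, collapse = ", "))
    for (ty in tab$types) {
      e <- block[[ty]]
      if (is.null(e))
        stop("schema violation: ", env, "/", ty, " missing")
      for (p in c("V", "lambda", "dgref", "dgfree", "R")) {
        if (is.null(e[[p]]))
          stop("schema violation: ", env, "/", ty, "/", p, " missing")
        tab[[env]][ty, p] <- as.numeric(e[[p]])
      }
    }
  }
  tab
}

#' Build a slot grouping for genome encoding
#'
#' Every tunable slot (type x environment x parameter) is assigned to a
#' free-parameter group; slots of one group share a single genome value.
#'
#' Schemes: `"identity"` gives one group per slot (320 genes); `"class"`
#' groups by polarity class x parameter x environment (32 genes);
#' `"coarse"` groups by parameter kind with environment split only for the
#' free energies (6 genes: V, lambda, dGref water/chex, dGfree water/chex).
#'
#' @param scheme one of `"identity"`, `"class"`, `"coarse"`
#' @return data.frame with columns `type`, `env`, `param`, `group`
#' @export
make_grouping <- function(scheme = c("class", "identity", "coarse")) {
  scheme <- match.arg(scheme)
  reg <- bead_type_registry()
  g <- expand.grid(type = reg$name, env = c("water", "chex"),
                   param = .tunable_params, stringsAsFactors = FALSE)
  key <- switch(scheme,
    identity = paste(g$type, g$env, g$param),
    class = paste(reg$class[match(g$type, reg$name)], g$env, g$param),
    coarse = ifelse(g$param %in% c("dgref", "dgfree"),
                    paste(g$param, g$env), g$param))
  g$group <- as.integer(factor(key, levels = unique(key)))
  g
}

#' Discrete candidate value sets for each group
#'
#' For each free-parameter group a discrete grid of candidate values is
#' generated around the mean of the seeded initial values of its slots:
#' multiplicative for the positive-definite V and lambda, additive for the
#' free energies.  These grids are used both for population initialization
#' and for mutation.
#'
#' @param table seeded `cg_parameter_table`
#' @param grouping data.frame from [make_grouping()]
#' @param n_values grid size per gene
#' @param spread half-width of the multiplicative grid (fraction) and
#'   scaling of the additive grid
#' @return list of numeric vectors, one per group (in group order)
#' @export
candidate_sets <- function(table, grouping, n_values = 7, spread = 0.4) {
  ngroup <- max(grouping$group)
  sets <- vector("list", ngroup)
  for (gi in seq_len(ngroup)) {
    rows <- grouping[grouping$group == gi, , drop = FALSE]
    vals <- mapply(function(ty, env, p) table[[env]][ty, p],
                   rows$type, rows$env, rows$param)
    base <- mean(vals)
    if (rows$param[1] %in% c("V", "lambda")) {
      sets[[gi]] <- base * seq(1 - spread, 1 + spread, length.out = n_values)
    } else {
      half <- spread * (abs(base) + 2)
      sets[[gi]] <- base + seq(-half, half, length.out = n_values)
    }
  }
  sets
}

#' Encode a parameter table as a genome / decode a genome into a table
#'
#' `encode` extracts one value per group (slots in a group must agree);
#' `decode` writes the genome values back into every slot of each group.
#' `decode(encode(t))` reproduces `t` for any grouping-consistent table.
#'
#' @param table a `cg_parameter_table`
#' @param grouping data.frame from [make_grouping()]
#' @param genome numeric vector, one value per group
#' @param template table supplying the fixed entries (R and slot layout)
#' @return `encode`: numeric genome; `decode`: a `cg_parameter_table`
#' @export
encode_genome <- function(table, grouping) {
  ngroup <- max(grouping$group)
  genome <- numeric(ngroup)
  for (gi in seq_len(ngroup)) {
    rows <- grouping[grouping$group == gi, , drop = FALSE]
    vals <- mapply(function(ty, env, p) table[[env]][ty, p],
                   rows$type, rows$env, rows$param)
    if (diff(range(vals)) > 1e-9 * (abs(mean(vals)) + 1e-9))
      stop("table is not consistent with the grouping (group ", gi, ")")
    genome[gi] <- vals[1]
  }
  genome
}

#' @rdname encode_genome
#' @export
decode_genome <- function(genome, grouping, template) {
  ngroup <- max(grouping$group)
  if (length(genome) != ngroup)
    stop("genome length ", length(genome), " != group count ", ngroup)
  tab <- template
  for (r in seq_len(nrow(grouping))) {
    tab[[grouping$env[r]]][grouping$type[r], grouping$param[r]] <-
      genome[grouping$group[r]]
  }
  tab
}
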