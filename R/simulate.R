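# Seeded synthetic catalog generator.  Genotypes are drawn from a mixture
# of archetypes modelled on the kinds of mouse models the curated corpus
# contains (simple knock-outs, conditional cre/loxP models, transgenic
# overexpression models, docking-site knock-ins, engineered deletions,
# digenic crosses, ...).  Every terminal flow-chart box and every exclusion
# reason is reachable at the default mixture.

SIM_TEMPLATES <- c(
  single_gene = 0.45,          # B1: causative mutation in one gene
  conditional_floxed = 0.12,   # B3: floxed gene + cre tool, conditional
  digenic = 0.08,              # excluded: two mutated genes, no cargo
  transgene_cargo = 0.06,      # B8: transgene expressing one mouse gene
  knockin_mismatch = 0.04,     # excluded: knock-in expressing another gene
  docking_cargo = 0.04,        # B10: docking-site knock-in with cargo
  multigenic = 0.03,           # B4: deletion region (+ reporter tool)
  transgene_match = 0.03,      # B9: transgene expressing the mutated gene
  multi_cargo_transgene = 0.03,# B6: transgene with several cargo genes
  nonmouse_cargo = 0.03,       # excluded: non-mouse cargo gene
  rosa_no_cargo = 0.02,        # excluded: Rosa26 insert, no recorded cargo
  self_expressed = 0.02,       # B11: conditional knock-in of its own gene
  multi_cargo_plus_gene = 0.02,# excluded: cargo transgene + mutated gene
  wild_type_only = 0.01,       # excluded: all alleles filtered out
  double_region = 0.01,        # excluded: two deletion regions
  region_plus_gene = 0.01      # excluded: region + outside gene
)

#' Parameters for the synthetic catalog generator
#'
#' @param n_genotypes Number of genotypes to generate.
#' @param n_genes,n_transgenes,n_regions Sizes of the shared marker pools.
#' @param region_size Integer range (min, max) of genes per deletion
#'   region.
#' @param mixture Named non-negative weights over the genotype archetypes
#'   (see `generollup:::SIM_TEMPLATES` for names and defaults); normalized
#'   to sum to 1.
#' @param annotations_per_genotype Mean number of source annotations per
#'   genotype (at least one is always assigned).
#' @param p_disease Probability that an annotation is an OMIM disease term
#'   rather than an MP phenotype term.
#' @param seed Non-negative integer; identical params and seed give an
#'   identical catalog.
#' @return A list of class `"gr_sim_params"`.
#' @export
simulation_params <- function(n_genotypes = 200, n_genes = 150,
                              n_transgenes = 40, n_regions = 4,
                              region_size = c(3L, 12L),
                              mixture = SIM_TEMPLATES,
                              annotations_per_genotype = 1.5,
                              p_disease = 0.15, seed = 1L) {
  stopifnot(n_genotypes >= 0, n_genes >= 0, n_transgenes >= 0,
            n_regions >= 0, length(region_size) == 2L,
            region_size[1] >= 1, region_size[2] >= region_size[1],
            annotations_per_genotype >= 0,
            p_disease >= 0, p_disease <= 1,
            is.numeric(seed), length(seed) == 1L, seed >= 0)
  full <- SIM_TEMPLATES * 0
  if (is.null(names(mixture)) && length(mixture) == length(full)) {
    names(mixture) <- names(full)
  }
  bad <- setdiff(names(mixture), names(full))
  if (length(bad)) {
    stop(sprintf("unknown archetype(s) in mixture: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(mixture < 0) || sum(mixture) <= 0) {
    stop("mixture weights must be non-negative and sum to > 0", call. = FALSE)
  }
  full[names(mixture)] <- mixture
  # Feasibility: every archetype with positive weight needs its pools.
  need_genes <- setdiff(names(full)[full > 0], "rosa_no_cargo")
  if (length(need_genes) && n_genes < 4) {
    stop("mixture requires genes but n_genes < 4", call. = FALSE)
  }
  needs_tg <- c("transgene_cargo", "transgene_match", "multi_cargo_transgene",
                "multi_cargo_plus_gene", "wild_type_only")
  if (any(full[needs_tg] > 0) && n_transgenes < 1) {
    stop("mixture requires transgenes but n_transgenes = 0", call. = FALSE)
  }
  needs_rg <- c("multigenic", "double_region", "region_plus_gene")
  if (any(full[needs_rg] > 0) && n_regions < 2) {
    stop("mixture requires at least 2 region markers", call. = FALSE)
  }
  structure(
    list(n_genotypes = as.integer(n_genotypes), n_genes = as.integer(n_genes),
         n_transgenes = as.integer(n_transgenes),
         n_regions = as.integer(n_regions),
         region_size = as.integer(region_size),
         mixture = full / sum(full),
         annotations_per_genotype = annotations_per_genotype,
         p_disease = p_disease, seed = as.integer(seed)),
    class = "gr_sim_params"
  )
}

pick <- function(x, n = 1L, replace = FALSE) x[sample.int(length(x), n, replace = replace)]

#' Generate a synthetic catalog and annotation table
#'
#' Reproducible by seed (the caller's RNG state is left untouched).  The
#' generator emulates the structural variety of a curated mouse-model
#' corpus — allele attributes, generation methods, conditional flags,
#' expressed-gene cargo — but not its scale, its ontology structure, or
#' real strain genetics; synthetic term ids use a reserved high-numbered
#' MP:/OMIM: range.
#'
#' @param params A [simulation_params()].
#' @return A list with `catalog`, `annotations`, and `archetypes` (named
#'   character vector: genotype id -> generating archetype, useful for
#'   stratified checks).
#' @export
#' @examples
#' sim <- simulate_catalog(simulation_params(n_genotypes = 25, seed = 42))
#' sim$catalog
simulate_catalog <- function(params = simulation_params()) {
  stopifnot(inherits(params, "gr_sim_params"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  gene_ids <- sprintf("sim:g%04d", seq_len(params$n_genes))
  markers <- lapply(seq_len(params$n_genes), function(i)
    marker(gene_ids[i], sprintf("Simg%04d", i), "gene"))
  dock <- list(rosa = "sim:rosa26", col1a1 = "sim:col1a1", hprt = "sim:hprt")
  markers <- c(markers, list(
    marker(dock$rosa, "Gt(ROSA)26Sor", "gene"),
    marker(dock$col1a1, "Col1a1", "gene"),
    marker(dock$hprt, "Hprt", "gene")
  ))
  tg_ids <- sprintf("sim:tg%03d", seq_len(params$n_transgenes))
  markers <- c(markers, lapply(seq_len(params$n_transgenes), function(i)
    marker(tg_ids[i], sprintf("Tg(Sim)%03d", i), "transgene")))
  region_ids <- sprintf("sim:del%02d", seq_len(params$n_regions))
  region_members <- list()
  if (params$n_regions > 0) {
    for (i in seq_len(params$n_regions)) {
      k <- sample(seq(params$region_size[1], params$region_size[2]), 1L)
      region_members[[i]] <- pick(gene_ids, min(k, length(gene_ids)))
      markers <- c(markers, list(
        marker(region_ids[i], sprintf("Del(Sim)%02d", i),
               "multi_genic_region", region_genes = region_members[[i]])
      ))
    }
  }

  alleles <- list()
  genotypes <- list()
  archetypes <- character()
  counter <- 0L
  add_allele <- function(...) {
    counter <<- counter + 1L
    a <- allele(sprintf("sim:a%05d", counter), ...)
    alleles[[length(alleles) + 1L]] <<- a
    a$id
  }
  mk_wt <- function(gene) {
    add_allele(sprintf("Wt%05d<+>", counter + 1L), "other",
               mutated_markers = gene, is_wild_type = TRUE)
  }
  mk_null <- function(gene) {
    add_allele(sprintf("Sim%05d<tm>", counter + 1L), "targeted",
               attributes = "null_knockout", mutated_markers = gene)
  }
  mk_cre_tg <- function() {
    add_allele(sprintf("Tg(Sim-cre)%05d", counter + 1L), "transgenic",
               attributes = "recombinase", mutated_markers = pick(tg_ids))
  }
  mk_cargo_tg <- function(cargo) {
    add_allele(sprintf("Tg(Sim-cargo)%05d", counter + 1L), "transgenic",
               attributes = "inserted_expressed_sequence",
               mutated_markers = pick(tg_ids),
               expressed_genes = lapply(cargo, expressed_gene))
  }

  templates <- list(
    single_gene = function() {
      g <- pick(gene_ids)
      a <- mk_null(g)
      if (stats::runif(1) < 0.3) {
        list(pairs = list(allele_pair(a, mk_wt(g))), conditional = FALSE)
      } else {
        list(pairs = list(allele_pair(a, a)), conditional = FALSE)
      }
    },
    conditional_floxed = function() {
      g <- pick(gene_ids)
      a <- add_allele(sprintf("Sim%05d<tm(flox)>", counter + 1L), "targeted",
                      mutated_markers = g)
      list(pairs = list(allele_pair(a, a), allele_pair(mk_cre_tg())),
           conditional = TRUE)
    },
    wild_type_only = function() {
      gs <- pick(gene_ids, 2L)
      # two wild-type pairs plus a pure reporter transgene: everything a tool
      rep_tg <- add_allele(sprintf("Tg(Sim-rep)%05d", counter + 1L),
                           "transgenic", attributes = "reporter",
                           mutated_markers = pick(tg_ids))
      w1 <- mk_wt(gs[1]); w2 <- mk_wt(gs[2])
      list(pairs = list(allele_pair(w1, w1), allele_pair(w2, w2),
                        allele_pair(rep_tg)),
           conditional = FALSE)
    },
    digenic = function() {
      gs <- pick(gene_ids, 2L)
      a1 <- mk_null(gs[1]); a2 <- mk_null(gs[2])
      list(pairs = list(allele_pair(a1, a1), allele_pair(a2, a2)),
           conditional = FALSE)
    },
    multigenic = function() {
      r <- pick(seq_along(region_ids))
      a <- add_allele(sprintf("Del(Sim)%05d", counter + 1L), "targeted",
                      attributes = "null_knockout",
                      mutated_markers = region_ids[r])
      pairs <- list(allele_pair(a))
      if (stats::runif(1) < 0.5) {
        rep_tg <- add_allele(sprintf("Tg(Sim-rep)%05d", counter + 1L),
                             "transgenic", attributes = "reporter",
                             mutated_markers = pick(tg_ids))
        pairs <- c(pairs, list(allele_pair(rep_tg)))
      }
      list(pairs = pairs, conditional = FALSE)
    },
    double_region = function() {
      rs <- pick(seq_along(region_ids), 2L)
      a1 <- add_allele(sprintf("Del(Sim)%05d", counter + 1L), "targeted",
                       mutated_markers = region_ids[rs[1]])
      a2 <- add_allele(sprintf("Del(Sim)%05d", counter + 1L), "targeted",
                       mutated_markers = region_ids[rs[2]])
      list(pairs = list(allele_pair(a1), allele_pair(a2)),
           conditional = FALSE)
    },
    region_plus_gene = function() {
      r <- pick(seq_along(region_ids))
      outside <- setdiff(gene_ids, region_members[[r]])
      a1 <- add_allele(sprintf("Del(Sim)%05d", counter + 1L), "targeted",
                       mutated_markers = region_ids[r])
      a2 <- mk_null(pick(outside))
      list(pairs = list(allele_pair(a1), allele_pair(a2, a2)),
           conditional = FALSE)
    },
    transgene_cargo = function() {
      list(pairs = list(allele_pair(mk_cargo_tg(pick(gene_ids)))),
           conditional = FALSE)
    },
    transgene_match = function() {
      g <- pick(gene_ids)
      a <- mk_null(g)
      list(pairs = list(allele_pair(a, a), allele_pair(mk_cargo_tg(g))),
           conditional = FALSE)
    },
    multi_cargo_transgene = function() {
      k <- sample(2:3, 1L)
      list(pairs = list(allele_pair(mk_cargo_tg(pick(gene_ids, k)))),
           conditional = FALSE)
    },
    multi_cargo_plus_gene = function() {
      gs <- pick(gene_ids, 3L)
      a <- mk_null(gs[3])
      list(pairs = list(allele_pair(mk_cargo_tg(gs[1:2])),
                        allele_pair(a, a)),
           conditional = FALSE)
    },
    docking_cargo = function() {
      site <- pick(c(dock$rosa, dock$col1a1, dock$hprt))
      a <- add_allele(sprintf("Sim%05d<tm(cargo)>", counter + 1L), "targeted",
                      attributes = "inserted_expressed_sequence",
                      mutated_markers = site,
                      expressed_genes = list(expressed_gene(pick(gene_ids))))
      list(pairs = list(allele_pair(a, a)), conditional = FALSE)
    },
    rosa_no_cargo = function() {
      a <- add_allele(sprintf("Sim%05d<tm(viral)>", counter + 1L), "targeted",
                      attributes = "inserted_expressed_sequence",
                      mutated_markers = dock$rosa)
      list(pairs = list(allele_pair(a, a)), conditional = FALSE)
    },
    nonmouse_cargo = function() {
      g <- pick(gene_ids)
      a <- add_allele(sprintf("Sim%05d<tm(hum)>", counter + 1L), "targeted",
                      attributes = c("inserted_expressed_sequence",
                                     "null_knockout"),
                      mutated_markers = g,
                      expressed_genes = list(
                        expressed_gene(sprintf("HUM%05d", counter + 1L),
                                       "non_mouse")))
      list(pairs = list(allele_pair(a, a)), conditional = FALSE)
    },
    knockin_mismatch = function() {
      gs <- pick(gene_ids, 2L)
      a <- add_allele(sprintf("Sim%05d<tm(ki)>", counter + 1L), "targeted",
                      attributes = c("inserted_expressed_sequence",
                                     "null_knockout"),
                      mutated_markers = gs[1],
                      expressed_genes = list(expressed_gene(gs[2])))
      list(pairs = list(allele_pair(a, a)), conditional = FALSE)
    },
    self_expressed = function() {
      g <- pick(gene_ids)
      a <- add_allele(sprintf("Sim%05d<tm(self)>", counter + 1L), "targeted",
                      attributes = "inserted_expressed_sequence",
                      mutated_markers = g,
                      expressed_genes = list(expressed_gene(g)))
      list(pairs = list(allele_pair(a, a), allele_pair(mk_cre_tg())),
           conditional = TRUE)
    }
  )

  weights <- params$mixture
  kinds <- if (params$n_genotypes > 0) {
    sample(names(weights), params$n_genotypes, replace = TRUE, prob = weights)
  } else character()

  for (i in seq_len(params$n_genotypes)) {
    gid <- sprintf("sim:gt%05d", i)
    made <- templates[[kinds[i]]]()
    genotypes[[length(genotypes) + 1L]] <-
      genotype(gid, made$pairs, is_conditional = made$conditional,
               strain_background = pick(c("C57BL/6J", "129S1/SvImJ",
                                          "involves: mixed", "NOD", "FVB/N")))
    archetypes[gid] <- kinds[i]
  }

  ann <- list()
  for (g in genotypes) {
    n_terms <- max(1L, stats::rpois(1L, params$annotations_per_genotype))
    for (k in seq_len(n_terms)) {
      disease <- stats::runif(1) < params$p_disease
      ann[[length(ann) + 1L]] <- data.frame(
        genotype_id = g$id,
        term_id = if (disease) sprintf("OMIM:9%06d", sample.int(500000L, 1L))
                  else sprintf("MP:97%05d", sample.int(90000L, 1L)),
        ontology = if (disease) "disease" else "phenotype",
        qualifier = "",
        reference = sprintf("J:%06d", sample.int(999999L, 1L)),
        stringsAsFactors = FALSE
      )
    }
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(genotype_id = character(), term_id = character(),
               ontology = character(), qualifier = character(),
               reference = character(), stringsAsFactors = FALSE)

  list(catalog = catalog(markers, alleles, genotypes),
       annotations = annotations,
       archetypes = archetypes)
}
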