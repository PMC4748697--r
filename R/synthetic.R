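# Seeded synthetic-community generator: rank-structured taxonomy, Markov
# genomes whose compositional similarity decays with taxonomic distance,
# fragmentation into contigs/scaffolds, planted marker regions, reference
# collections with leave-out masking, and ground truth.

#' Specification of a synthetic community
#'
#' The defaults are a desk-scale analogue of a simulated benchmark
#' community: 10 species in 5 genera, ~0.6 Mb genomes, a 2 Mb contig
#' sample, and 3 reference-only sibling species per genus standing in for
#' the public reference collection.
#'
#' @param n_taxa Number of community species.
#' @param species_per_genus,genera_per_family,families_per_order Taxonomy
#'   shape (ceiling grouping).
#' @param ref_species_per_genus Reference-only sibling species added under
#'   every community genus.
#' @param genome_bp Community genome length (bp).
#' @param ref_reserve_bp Trailing genome portion reserved as reference
#'   data (never sampled into contigs).
#' @param ref_genome_bp Genome length of reference-only species.
#' @param sample_bp Total contig bp drawn for the sample.
#' @param abundance `"uniform"` or `"lognormal"` community abundance.
#' @param lognormal_meanlog,lognormal_sdlog Log-normal abundance
#'   parameters.
#' @param contig_meanlog,contig_sdlog,contig_min,contig_max Contig length
#'   distribution (log-normal, clipped).
#' @param scaffold_geom_p,scaffold_max Scaffold sizes are
#'   `1 + Geom(p)` contigs, capped.
#' @param marker_density Planted marker regions per Mb of contig.
#' @param marker_len Marker region length (bp).
#' @param markers_per_ref_taxon Marker reference sequences extracted per
#'   reference species.
#' @param divergence Named per-rank signature perturbation magnitudes
#'   (log-scale sd on Markov transition rows); larger near the root so
#'   that compositional distance grows with taxonomic distance.
#' @param seed RNG seed.
#' @return List of class `community_spec`.
#' @export
community_spec <- function(n_taxa = 10L,
                           species_per_genus = 2L,
                           genera_per_family = 3L,
                           families_per_order = 2L,
                           ref_species_per_genus = 3L,
                           genome_bp = 6e5,
                           ref_reserve_bp = 3.5e5,
                           ref_genome_bp = 3.2e5,
                           sample_bp = 2e6,
                           abundance = c("uniform", "lognormal"),
                           lognormal_meanlog = 0,
                           lognormal_sdlog = 1,
                           contig_meanlog = log(8000),
                           contig_sdlog = 0.45,
                           contig_min = 1000L,
                           contig_max = 20000L,
                           scaffold_geom_p = 0.4,
                           scaffold_max = 6L,
                           marker_density = 50,
                           marker_len = 750L,
                           markers_per_ref_taxon = 12L,
                           divergence = c(phylum = 0.8, class = 0.55,
                                          order = 0.45, family = 0.4,
                                          genus = 0.3, species = 0.18),
                           seed = 1L) {
  abundance <- match.arg(abundance)
  stopifnot(n_taxa >= 2, genome_bp > ref_reserve_bp,
            contig_min <= contig_max, all(divergence > 0))
  structure(as.list(environment()), class = "community_spec")
}

#' Generate the community taxonomy
#'
#' Builds a rank ladder root > phylum > class > order > family > genus >
#' species, grouping the `n_taxa` community species per the shape
#' parameters and adding `ref_species_per_genus` reference-only sibling
#' species under each genus. Deterministic.
#'
#' @param spec A [community_spec()].
#' @return A [taxonomy()] object with extra fields `community_leaves` and
#'   `reference_leaves`.
#' @export
generate_taxonomy <- function(spec) {
  n <- spec$n_taxa
  sp <- sprintf("s%02d", seq_len(n))
  genus_of <- sprintf("g%d", ((seq_len(n) - 1L) %/%
                                spec$species_per_genus) + 1L)
  genera <- unique(genus_of)
  fam_of_g <- sprintf("f%d", ((seq_along(genera) - 1L) %/%
                                spec$genera_per_family) + 1L)
  fams <- unique(fam_of_g)
  ord_of_f <- sprintf("o%d", ((seq_along(fams) - 1L) %/%
                                spec$families_per_order) + 1L)
  ords <- unique(ord_of_f)

  rows <- list(data.frame(taxon_id = "root", parent_id = "root",
                          rank = "no rank"))
  rows <- c(rows, list(
    data.frame(taxon_id = "p1", parent_id = "root", rank = "phylum"),
    data.frame(taxon_id = "c1", parent_id = "p1", rank = "class")))
  for (o in ords)
    rows <- c(rows, list(data.frame(taxon_id = o, parent_id = "c1",
                                    rank = "order")))
  for (i in seq_along(fams))
    rows <- c(rows, list(data.frame(taxon_id = fams[i],
                                    parent_id = ord_of_f[i],
                                    rank = "family")))
  for (i in seq_along(genera))
    rows <- c(rows, list(data.frame(taxon_id = genera[i],
                                    parent_id = fam_of_g[i],
                                    rank = "genus")))
  for (i in seq_len(n))
    rows <- c(rows, list(data.frame(taxon_id = sp[i],
                                    parent_id = genus_of[i],
                                    rank = "species")))
  refs <- character(0)
  for (g in genera)
    for (j in seq_len(spec$ref_species_per_genus)) {
      id <- paste0(g, "x", j)
      refs <- c(refs, id)
      rows <- c(rows, list(data.frame(taxon_id = id, parent_id = g,
                                      rank = "species")))
    }
  tree <- taxonomy(do.call(rbind, rows))
  tree$community_leaves <- sp
  tree$reference_leaves <- refs
  tree
}

.perturb_chain <- function(chain, sigma) {
  logits <- log(chain) + stats::rnorm(length(chain), 0, sigma)
  m <- exp(logits)
  m / rowSums(m)
}

.digits_to_dna <- function(d) intToUtf8(c(65L, 84L, 71L, 67L)[d + 1L])

#' Generate per-leaf genomes
#'
#' Every leaf genome is sampled from an order-3 Markov chain. Transition
#' matrices are inherited down the tree with per-rank log-scale
#' perturbations from the divergence ladder, so compositional distance
#' correlates with taxonomic distance.
#'
#' @param tree Taxonomy from [generate_taxonomy()].
#' @param spec A [community_spec()].
#' @param seed RNG seed (default `spec$seed`).
#' @return Named character vector of leaf genomes.
#' @export
generate_genomes <- function(tree, spec, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  base <- matrix(stats::rgamma(256, shape = 3), 64, 4)
  base <- base / rowSums(base)
  chains <- list(); chains[[tree$root]] <- base
  kids <- tax_children(tree)
  queue <- tree$root
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (ch in kids[[cur]]) {
      rk <- tree$rank[[ch]]
      sigma <- if (rk %in% names(spec$divergence))
        spec$divergence[[rk]] else 0.1
      chains[[ch]] <- .perturb_chain(chains[[cur]], sigma)
      queue <- c(queue, ch)
    }
  }
  leaves <- c(tree$community_leaves, tree$reference_leaves)
  genomes <- stats::setNames(character(length(leaves)), leaves)
  for (lf in leaves) {
    len <- if (lf %in% tree$community_leaves) spec$genome_bp
           else spec$ref_genome_bp
    genomes[[lf]] <- .digits_to_dna(cpp_markov_generate(chains[[lf]],
                                                        as.integer(len)))
  }
  genomes
}

#' Leave-out scenario
#'
#' Masks reference data of the community lineages up to the stated rank,
#' independently for the genome reference collection (RS) and the marker
#' reference collection (MG); `"none"` masks nothing.
#'
#' @param rs,mg `"none"`, `"strain"`, `"species"` or `"genus"`.
#' @return List of class `leave_out_scenario`.
#' @export
leave_out_scenario <- function(rs = "none", mg = "none") {
  choices <- c("none", "strain", "species", "genus")
  stopifnot(rs %in% choices, mg %in% choices)
  structure(list(rs = rs, mg = mg), class = "leave_out_scenario")
}

# taxa whose reference data a mask removes: descendants of the
# rank-ancestors of the community leaves (the community taxa themselves
# at that rank and everything below)
.masked_taxa <- function(tree, rank) {
  if (rank == "none") return(character(0))
  if (rank == "strain") rank <- "strain"   # no strain nodes -> leaves only
  anc <- unique(vapply(tree$community_leaves, function(s) {
    a <- ancestor_at_rank(tree, s, rank)
    if (is.na(a)) s else a
  }, character(1)))
  unique(unlist(lapply(anc, tax_descendants, tree = tree)))
}

#' Generate the contig sample, references and ground truth
#'
#' Draws contigs per the abundance model from the sampling portion of
#' each community genome, groups them into scaffolds, plants labeled
#' marker regions at the configured density (forward strand), and builds
#' the reference catalog and marker reference collection from held-out
#' genome portions with the leave-out masking applied independently to
#' each collection.
#'
#' @param tree Taxonomy from [generate_taxonomy()].
#' @param genomes Genomes from [generate_genomes()].
#' @param spec A [community_spec()].
#' @param scenario A [leave_out_scenario()].
#' @param seed RNG seed (default `spec$seed + 1`).
#' @return List with `contigs`, `lengths`, `scaffold_map`, `truth`,
#'   `hits`, `catalog` ([reference_catalog()]), `mg_seqs`, `mg_labels`,
#'   `abundances`, `scenario`.
#' @export
generate_sample <- function(tree, genomes, spec,
                            scenario = leave_out_scenario(),
                            seed = spec$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  community <- tree$community_leaves
  n <- length(community)
  ab <- switch(spec$abundance,
               uniform = rep(1 / n, n),
               lognormal = {
                 w <- stats::rlnorm(n, spec$lognormal_meanlog,
                                    spec$lognormal_sdlog)
                 w / sum(w)
               })
  names(ab) <- community

  contigs <- character(0)
  truth_rows <- list(); scaf_rows <- list(); hit_rows <- list()
  for (sp_id in community) {
    g <- genomes[[sp_id]]
    pool_len <- nchar(g) - spec$ref_reserve_bp
    target <- ab[[sp_id]] * spec$sample_bp
    cum <- 0; i <- 0L; ids <- character(0)
    while (cum < target) {
      i <- i + 1L
      clen <- round(stats::rlnorm(1, spec$contig_meanlog,
                                  spec$contig_sdlog))
      clen <- max(spec$contig_min, min(spec$contig_max, clen, pool_len))
      start <- sample.int(pool_len - clen + 1L, 1L)
      id <- sprintf("%s_c%03d", sp_id, i)
      contigs[[id]] <- substr(g, start, start + clen - 1L)
      ids <- c(ids, id)
      cum <- cum + clen
      truth_rows[[id]] <- data.frame(seq_id = id, taxon_id = sp_id,
                                     length = clen,
                                     stringsAsFactors = FALSE)
      nh <- stats::rpois(1, clen * spec$marker_density / 1e6)
      nh <- min(nh, max(0L, clen %/% spec$marker_len))
      if (nh > 0L) {
        starts <- sample.int(clen - spec$marker_len + 1L, nh)
        hit_rows[[id]] <- data.frame(
          contig_id = id, start = starts - 1L,
          end = starts - 1L + spec$marker_len,
          gene = sample(sprintf("mg%02d", 1:34), nh, replace = TRUE),
          strand = "+", frame = 0L, stringsAsFactors = FALSE)
      }
    }
    # consecutive contigs into scaffolds of 1 + Geom(p), capped
    j <- 1L; sc <- 0L
    while (j <= length(ids)) {
      sc <- sc + 1L
      size <- min(1L + stats::rgeom(1, spec$scaffold_geom_p),
                  spec$scaffold_max, length(ids) - j + 1L)
      scaf_rows[[paste(sp_id, sc)]] <- data.frame(
        scaffold_id = sprintf("%s_sc%02d", sp_id, sc),
        contig_id = ids[j:(j + size - 1L)], stringsAsFactors = FALSE)
      j <- j + size
    }
  }

  # reference catalog: held-out community portions + full reference-only
  # genomes, minus the RS mask
  rs_masked <- .masked_taxa(tree, scenario$rs)
  bp_rows <- list(); ref_seqs <- list()
  for (sp_id in community) {
    if (sp_id %in% rs_masked) next
    g <- genomes[[sp_id]]
    seq <- substr(g, nchar(g) - spec$ref_reserve_bp + 1L, nchar(g))
    bp_rows[[sp_id]] <- data.frame(taxon_id = sp_id, bp = nchar(seq))
    ref_seqs[[sp_id]] <- seq
  }
  for (r_id in tree$reference_leaves) {
    if (r_id %in% rs_masked) next
    bp_rows[[r_id]] <- data.frame(taxon_id = r_id,
                                  bp = nchar(genomes[[r_id]]))
    ref_seqs[[r_id]] <- genomes[[r_id]]
  }
  bp_df <- if (length(bp_rows) > 0L) do.call(rbind, bp_rows)
           else data.frame(taxon_id = character(0), bp = numeric(0))
  catalog <- reference_catalog(bp_df, ref_seqs)

  # marker reference collection, minus the MG mask
  mg_masked <- .masked_taxa(tree, scenario$mg)
  mg_seqs <- character(0); mg_rows <- list()
  for (sp_id in c(community, tree$reference_leaves)) {
    if (sp_id %in% mg_masked) next
    g <- genomes[[sp_id]]
    src <- if (sp_id %in% community)
      substr(g, nchar(g) - spec$ref_reserve_bp + 1L, nchar(g)) else g
    m <- spec$markers_per_ref_taxon
    starts <- round(seq(1L, nchar(src) - spec$marker_len + 1L,
                        length.out = m))
    ids <- sprintf("%s_mg%02d", sp_id, seq_len(m))
    pieces <- substring(src, starts, starts + spec$marker_len - 1L)
    names(pieces) <- ids
    mg_seqs <- c(mg_seqs, pieces)
    mg_rows[[sp_id]] <- data.frame(seq_id = ids, taxon_id = sp_id,
                                   stringsAsFactors = FALSE)
  }

  list(contigs = contigs,
       lengths = stats::setNames(nchar(contigs), names(contigs)),
       scaffold_map = do.call(rbind, c(scaf_rows,
                                       list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
       hits = do.call(rbind, c(hit_rows, list(make.row.names = FALSE))),
       catalog = catalog,
       mg_seqs = mg_seqs,
       mg_labels = do.call(rbind, c(mg_rows, list(make.row.names = FALSE))),
       abundances = ab, scenario = scenario)
}

#' Generate a full labeled community in one call
#'
#' @param spec A [community_spec()].
#' @param scenario A [leave_out_scenario()].
#' @return List: `tree`, `genomes`, and all elements of
#'   [generate_sample()].
#' @export
generate_community <- function(spec = community_spec(),
                               scenario = leave_out_scenario()) {
  tree <- generate_taxonomy(spec)
  genomes <- generate_genomes(tree, spec)
  c(list(tree = tree, genomes = genomes, spec = spec),
    generate_sample(tree, genomes, spec, scenario))
}

#' Write a community to disk in the pipeline's input formats
#'
#' FASTA contigs, scaffold/truth/hits/catalog TSVs, marker reference
#' FASTA + labels, and the taxonomy TSV.
#'
#' @param comm Output of [generate_community()].
#' @param dir Output directory.
#' @export
write_community <- function(comm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(comm$contigs),
                              file.path(dir, "contigs.fna"))
  utils::write.table(comm$scaffold_map, file.path(dir, "scaffolds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comm$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(comm$hits, file.path(dir, "marker_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(taxon_id = names(comm$catalog$bp), bp = comm$catalog$bp),
    file.path(dir, "catalog.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  refdir <- file.path(dir, "reference")
  dir.create(refdir, showWarnings = FALSE)
  for (t in names(comm$catalog$ref_seqs))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(comm$catalog$ref_seqs[[t]],
                                               t)),
      file.path(refdir, paste0(t, ".fna")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(comm$mg_seqs),
                              file.path(dir, "markers.fna"))
  utils::write.table(comm$mg_labels, file.path(dir, "marker_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_taxonomy_tsv(comm$tree, file.path(dir, "taxonomy.tsv"))
  invisible(dir)
}
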