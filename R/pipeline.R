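#' Run a curation pipeline stage by name
#'
#' Single programmatic entry point behind the command-line wrapper
#' (\code{inst/scripts/ssrcurate.R}): each subcommand reads its inputs,
#' calls the corresponding analysis functions and writes its documented
#' CSV/text outputs under \code{out_dir}.  A run log (\code{run_log.txt})
#' records the subcommand, seed and package version.
#'
#' Subcommands: \code{stats} (per-locus diversity table + long-format
#' allele frequencies), \code{dedupe} (replicate consolidation, match
#' groups, classification, error rate), \code{dendro} (Lynch similarity
#' matrix + UPGMA Newick), \code{parentage} (per-record verdicts +
#' match-rate summary), \code{structure} (replicate admixture runs,
#' aligned consensus Q), \code{evanno} (delta-K table + selected K),
#' \code{simulate} (synthetic collection + truth labels).
#'
#' @param subcommand one of the names above.
#' @param args named list of arguments for the stage; common ones:
#'   \code{genotypes} (path to a genotype table or an \code{SSRGenotypes}),
#'   \code{pedigrees} (path or data.frame), \code{seed}, \code{offset},
#'   plus stage-specific settings (\code{k_range}, \code{reps},
#'   \code{threshold}, simulator parameters, ...).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the in-memory results written.
#' @export
runCommand <- function(subcommand, args = list(), out_dir = ".") {
    sub <- match.arg(subcommand,
                     c("stats", "dedupe", "dendro", "parentage",
                       "structure", "evanno", "simulate"))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- args$seed
    logf <- file.path(out_dir, "run_log.txt")
    cat(sprintf("ssrcurate %s | subcommand=%s | seed=%s | %s\n",
                as.character(utils::packageVersion("ssrcurate")), sub,
                if (is.null(seed)) "none" else seed, format(Sys.time())),
        file = logf, append = TRUE)
    getx <- function() {
        x <- args$genotypes
        if (is.character(x)) x <- readGenotypes(x)
        if (!is(x, "SSRGenotypes")) stop("no genotype input supplied")
        if (!is.null(args$offset) && args$offset > 0)
            x <- applyTagOffset(x, args$offset)
        x
    }
    res <- switch(sub,
        stats = {
            x <- getx()
            st <- diversityStats(x,
                rare_threshold = args$rare_threshold %||% 0.05,
                hwe = isTRUE(args$hwe), seed = seed)
            utils::write.csv(st, file.path(out_dir, "locus_stats.csv"),
                             row.names = FALSE)
            af <- do.call(rbind, lapply(lociIds(x), function(l) {
                ft <- alleleFrequencies(x, l)
                data.frame(locus = l, allele = names(ft$freq),
                           frequency = unname(ft$freq))
            }))
            utils::write.csv(af, file.path(out_dir, "allele_frequencies.csv"),
                             row.names = FALSE)
            list(stats = st, frequencies = af)
        },
        dedupe = {
            x <- getx()
            n_total <- ncol(x)
            cons <- consolidateReplicates(x,
                min_overlap = args$min_overlap %||% 8L)
            groups <- buildMatchGroups(cons$matrix,
                min_overlap = args$min_overlap %||% 8L)
            ped <- .getPed(args)
            rep_ <- classifyGroups(groups, accessionMeta(cons$matrix),
                                   pedigrees = ped, n_total = n_total,
                                   homonyms = cons$homonyms)
            utils::write.csv(rep_$groups,
                             file.path(out_dir, "match_groups.csv"),
                             row.names = FALSE)
            utils::write.csv(cons$confirmations,
                             file.path(out_dir, "replicate_confirmations.csv"),
                             row.names = FALSE)
            utils::write.csv(cons$homonyms,
                             file.path(out_dir, "homonyms.csv"),
                             row.names = FALSE)
            txt <- utils::capture.output(print(rep_))
            writeLines(txt, file.path(out_dir, "curation_report.txt"))
            rep_
        },
        dendro = {
            x <- getx()
            s <- similarityMatrix(x)
            utils::write.csv(s, file.path(out_dir, "similarity.csv"))
            tree <- upgma(s)
            toNewick(tree, file.path(out_dir, "dendrogram.nwk"))
            list(similarity = s, tree = tree)
        },
        parentage = {
            x <- getx()
            ped <- .getPed(args)
            v <- verifyPedigrees(ped, x,
                                 min_loci = args$min_loci %||% 8L,
                                 allow_null = isTRUE(args$allow_null))
            utils::write.csv(v$results,
                             file.path(out_dir, "parentage_verdicts.csv"),
                             row.names = FALSE)
            utils::write.csv(v$summary,
                             file.path(out_dir, "parentage_summary.csv"),
                             row.names = FALSE)
            v
        },
        structure = {
            x <- getx()
            scan <- structureScan(x,
                k_range = args$k_range %||% 1:6,
                reps = args$reps %||% 3,
                burnin = args$burnin %||% 2000,
                mcmc = args$mcmc %||% 8000,
                seed = seed %||% 1)
            for (k in names(scan$runs)) {
                al <- if (length(scan$runs[[k]]) > 1L)
                    alignReplicates(scan$runs[[k]])$consensus
                else scan$runs[[k]][[1L]]$Q
                utils::write.csv(al,
                    file.path(out_dir, sprintf("Q_consensus_K%s.csv", k)))
            }
            lnp <- data.frame(K = rep(as.integer(names(scan$lnP)),
                                      lengths(scan$lnP)),
                              lnP = unlist(scan$lnP, use.names = FALSE))
            utils::write.csv(lnp, file.path(out_dir, "lnP_by_K.csv"),
                             row.names = FALSE)
            scan
        },
        evanno = {
            lnP <- args[["lnP"]]
            if (is.null(lnP) && !is.null(args[["lnP_csv"]])) {
                df <- utils::read.csv(args[["lnP_csv"]])
                lnP <- split(df$lnP, df$K)
            }
            if (is.null(lnP)) stop("evanno needs lnP values (lnP or lnP_csv)")
            tab <- evannoTable(lnP)
            utils::write.csv(tab, file.path(out_dir, "evanno.csv"),
                             row.names = FALSE)
            k <- selectK(tab)
            cat(sprintf("selected K = %d\n", k),
                file = logf, append = TRUE)
            list(table = tab, K = k)
        },
        simulate = {
            sim_args <- args[names(args) %in% names(formals(simulateCollection))]
            sim <- do.call(simulateCollection, sim_args)
            writeGenotypes(sim$genotypes,
                           file.path(out_dir, "genotypes.tsv"))
            utils::write.csv(accessionMeta(sim$genotypes),
                             file.path(out_dir, "metadata.csv"))
            utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                             row.names = FALSE)
            sim
        })
    invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.getPed <- function(args) {
    ped <- args$pedigrees
    if (is.character(ped)) ped <- readPedigrees(ped)
    ped
}
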