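# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's stream.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

# Write a data.frame as TSV (no quoting, no row names) -- the package's
# uniform table format.
writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

# Write a named matrix as TSV with an id first column.
writeMatrixTsv <- function(m, path, idCol = "gene_id") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- idCol
    writeTsv(df, path)
}

#' Positional biotype labels
#'
#' The seven positional lncRNA biotype labels used throughout the package:
#' divergent head-to-head (`XH`), convergent tail-to-tail (`XT`), antisense
#' containing the coding gene (`XO`), antisense contained in the coding gene
#' (`XI`), sense downstream (`SD`), sense upstream (`SU`) and intergenic
#' (`IG`).
#'
#' @return character vector of the seven labels.
#' @examples biotypeLabels()
#' @export
biotypeLabels <- function() c("XH", "XT", "XO", "XI", "SD", "SU", "IG")
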