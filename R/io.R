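#' Export a network realization to plain-text files
#'
#' Writes `neurons.csv` (positions, types, labels), `edges.csv` (one row per
#' synapse with source tag and jitter), `lgn_assignments.csv` and a
#' `manifest.json` holding the seed, scale and content checksums. Since
#' realizations are fully determined by `(scale_n, seed, rule)`, the
#' manifest suffices to regenerate the network with [build_network()]; the
#' CSV tables are for inspection and external tools.
#'
#' @param net A connected `network_realization`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "network_realization"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  neurons <- data.frame(
    id = seq_len(net$n), x = net$pos[, 1], y = net$pos[, 2],
    type = net$type, hypercolumn = net$hc, wedge_angle = net$wedge_angle,
    complex = net$complex, lgn_count = net$lgn_count
  )
  utils::write.csv(neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE, quote = FALSE)
  edge_frame <- function(pre_list, jit_list, source) {
    data.frame(post = rep.int(seq_len(net$n), lengths(pre_list)),
               pre = unlist(pre_list, use.names = FALSE),
               source = source,
               jitter = unlist(jit_list, use.names = FALSE))
  }
  adj <- net$adjacency
  edges <- rbind(edge_frame(adj$pre_E, adj$jit_E, "E"),
                 edge_frame(adj$pre_I, adj$jit_I, "I"),
                 edge_frame(adj$pre_L6, adj$jit_L6, "L6"))
  utils::write.csv(edges, file.path(dir, "edges.csv"),
                   row.names = FALSE, quote = FALSE)
  lgn <- data.frame(post = rep.int(seq_len(net$n), lengths(net$lgn_input$cells)),
                    lgn_cell = unlist(net$lgn_input$cells, use.names = FALSE),
                    jitter = unlist(net$lgn_input$jit, use.names = FALSE))
  utils::write.csv(lgn, file.path(dir, "lgn_assignments.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c("neurons.csv", "edges.csv", "lgn_assignments.csv")
  jsonlite::write_json(
    list(package = "v1scale",
         scale_n = net$scale_n, seed = net$seed,
         n_neurons = net$n, n_E = sum(net$is_E),
         checksums = as.list(tools::md5sum(file.path(dir, files)))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
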