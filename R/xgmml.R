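# Minimal XGMML (eXtensible Graph Markup and Modeling Language) dialect, the
# XML graph format of the Cytoscape ecosystem. Nodes carry an id/label and
# arbitrary <att> children; edges reference node ids. The subset written here
# round-trips losslessly through read_xgmml_graph().

xgmml_ns <- "http://www.cs.rpi.edu/XGMML"

att_type <- function(v) {
  if (is.numeric(v)) "real" else if (is.logical(v)) "boolean" else "string"
}

att_chr <- function(v) {
  if (is.numeric(v)) sprintf("%.12g", v) else as.character(v)
}

write_xgmml_graph <- function(path, label, nodes, edges, directed = TRUE) {
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes),
            is.data.frame(edges),
            all(c("source", "target") %in% names(edges)))
  doc <- xml2::xml_new_root("graph", label = label,
                            directed = if (directed) "1" else "0",
                            xmlns = xgmml_ns)
  node_attrs <- setdiff(names(nodes), "id")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(doc, "node", id = nodes$id[i],
                              label = nodes$id[i])
    for (a in node_attrs) {
      v <- nodes[[a]][i]
      if (is.na(v)) next
      xml2::xml_add_child(nd, "att", name = a, value = att_chr(v),
                          type = att_type(nodes[[a]]))
    }
  }
  edge_attrs <- setdiff(names(edges), c("source", "target"))
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(doc, "edge", source = edges$source[i],
                              target = edges$target[i])
    for (a in edge_attrs) {
      v <- edges[[a]][i]
      if (is.na(v)) next
      xml2::xml_add_child(ed, "att", name = a, value = att_chr(v),
                          type = att_type(edges[[a]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

collect_atts <- function(el) {
  atts <- xml2::xml_find_all(el, "./att")
  if (!length(atts)) return(list())
  nm <- xml2::xml_attr(atts, "name")
  ty <- xml2::xml_attr(atts, "type")
  va <- xml2::xml_attr(atts, "value")
  out <- lapply(seq_along(nm), function(j) {
    switch(ty[j],
           real = as.numeric(va[j]),
           boolean = as.logical(va[j]),
           va[j])
  })
  stats::setNames(out, nm)
}

read_xgmml_graph <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed XGMML in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  label <- xml2::xml_attr(doc, "label")
  node_els <- xml2::xml_find_all(doc, "./node")
  edge_els <- xml2::xml_find_all(doc, "./edge")
  bind_attr_rows <- function(ids, att_list) {
    all_names <- unique(unlist(lapply(att_list, names)))
    cols <- lapply(all_names, function(a) {
      vals <- lapply(att_list, function(x) x[[a]])
      proto <- vals[[which(!vapply(vals, is.null, logical(1)))[1]]]
      vapply(vals, function(v) {
        if (is.null(v)) {
          if (is.numeric(proto)) NA_real_ else
            if (is.logical(proto)) NA else NA_character_
        } else v
      }, proto)
    })
    out <- c(ids, stats::setNames(cols, all_names))
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  nodes <- bind_attr_rows(list(id = xml2::xml_attr(node_els, "id")),
                          lapply(node_els, collect_atts))
  edges <- bind_attr_rows(list(source = xml2::xml_attr(edge_els, "source"),
                               target = xml2::xml_attr(edge_els, "target")),
                          lapply(edge_els, collect_atts))
  list(label = label, nodes = nodes, edges = edges,
       directed = identical(xml2::xml_attr(doc, "directed"), "1"))
}
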