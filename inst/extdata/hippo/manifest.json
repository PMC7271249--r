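{"files":["annotations.tsv","effects.tsv","expression.tsv","idmap.tsv","interactions.mitab","interologs.tsv","manifest.json","ontology.tsv","receptors.tsv","reliability.tsv","tfs.tsv"],"fixture":"hippo","contexts":["trophoblast","stem cell"]}
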