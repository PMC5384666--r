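# Default concept-mapping configuration: a Sequence Ontology derived genomic
# subtree (variant types as concepts, variant effects / features as
# modifiers), the annotation value modifiers, and the phenotype augmentation
# (protein-level concepts plus population demographics).
#
# SO accessions are a curated subset of sequenceontology.org; the file is
# replaceable, and correctness of the toolkit depends only on the maps being
# injective, not on these particular ids.
variant_types:
  - {name: SNV, code: "SO:0001483"}
  - {name: insertion, code: "SO:0000667"}
  - {name: deletion, code: "SO:0000159"}
effects:
  - name: missense_variant
    code: "SO:0001583"
    synonyms: [nonsynonymous SNV, nonsynonymous, missense]
  - name: stop_gained
    code: "SO:0001587"
    synonyms: [stopgain, stopgain SNV, nonsense]
  - name: stop_lost
    code: "SO:0001578"
    synonyms: [stoploss, stoploss SNV]
  - name: synonymous_variant
    code: "SO:0001819"
    synonyms: [synonymous SNV, synonymous]
  - name: frameshift_variant
    code: "SO:0001589"
    synonyms: [frameshift insertion, frameshift deletion, frameshift substitution]
  - name: inframe_variant
    code: "SO:0001650"
    synonyms: [nonframeshift insertion, nonframeshift deletion, nonframeshift substitution]
features:
  - {name: exon, code: "SO:0000147", synonyms: [exonic]}
  - {name: splice_site, code: "SO:0000162", synonyms: [splicing]}
  - {name: UTR, code: "SO:0000203", synonyms: [UTR3, UTR5]}
annotation_modifiers:
  - {slot: gene, name: Gene symbol, code: "MOD:GENE", value_kind: TEXT}
  - {slot: rs_number, name: dbSNP RS, code: "MOD:RS", value_kind: TEXT}
  - {slot: polyphen_hdiv, name: PolyPhen-2 HDIV score, code: "MOD:PPH_HDIV", value_kind: NUMERIC}
phenotype_numeric:
  - name: HLA-DQB1 log protein ratio
    code: "PHN:HLADQB1_RATIO"
    column: hladqb1_log_ratio
populations:
  - {name: CEU, code: "DEM:POP:CEU"}
  - {name: CHB, code: "DEM:POP:CHB"}
  - {name: YRI, code: "DEM:POP:YRI"}
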