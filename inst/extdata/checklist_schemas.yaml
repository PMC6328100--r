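# Checklist schema definitions for the six ENA Webin checklist types
# supported by flat2webin.
#
# Each checklist lists its columns in output order: the universal columns
# ORGANISM_NAME and ENV_SAMPLE first, then the marker-specific columns,
# then a documented subset of ENA's optional columns (alphabetical), and
# SEQUENCE always last (so that user-added columns such as LOCALITY can be
# inserted before it).  Column fields:
#
#   kind        text | integer | yes_no | enum
#   requirement mandatory | conditional | optional
#   feature     flat-file feature class the value is read from (if any)
#   qualifier   feature qualifier the value is read from (if any)
#   rule        special parsing rule applied instead of / on top of a plain
#               qualifier copy (see package documentation)
#   permitted   allowed values for kind=enum
#
# "synonyms" are the marker abbreviations recognized during the input audit;
# "synonym_patterns" maps a synonym token to the text patterns that count as
# a match inside gene/note/product/standard_name qualifier values (tokens
# without an entry match themselves).  Both lists are user-extensible.
#
# The ENA accession slot of each checklist (e.g. an ERT number) is left
# empty; fill it in if you track the upstream checklist versions.

synonym_patterns:
  rRNA: ["rRNA", "ribosomal RNA", "rDNA"]
  "5' ETS": ["5' ETS", "5′ ETS"]
  "3' ETS": ["3' ETS", "3′ ETS"]

optional_common: &optional_common
  - {name: clone,            kind: text, requirement: optional, feature: source, qualifier: clone}
  - {name: collection_date,  kind: text, requirement: optional, feature: source, qualifier: collection_date}
  - {name: country,          kind: text, requirement: optional, feature: source, qualifier: country}
  - {name: ecotype,          kind: text, requirement: optional, feature: source, qualifier: ecotype}
  - {name: haplotype,        kind: text, requirement: optional, feature: source, qualifier: haplotype}
  - {name: isolate,          kind: text, requirement: optional, feature: source, qualifier: isolate}
  - {name: lat_lon,          kind: text, requirement: optional, feature: source, qualifier: lat_lon}
  - {name: PCR_primers,      kind: text, requirement: optional, feature: source, qualifier: PCR_primers}
  - {name: specimen_voucher, kind: text, requirement: optional, feature: source, qualifier: specimen_voucher}
  - {name: strain,           kind: text, requirement: optional, feature: source, qualifier: strain}

universal_head: &universal_head
  - {name: ORGANISM_NAME, kind: text,   requirement: mandatory, feature: source, qualifier: organism}
  - {name: ENV_SAMPLE,    kind: yes_no, requirement: mandatory, rule: run_flag}

universal_tail: &universal_tail
  - {name: SEQUENCE, kind: text, requirement: mandatory, rule: sequence}

checklists:

  gene_intron:
    description: any gene intron (e.g. the trnL intron)
    ena_accession: ""
    synonyms: [trnL, trnG, rpl16, rps16, petD, intron]
    columns:
      - *universal_head
      - - {name: GENE,       kind: text,    requirement: mandatory, feature: gene,   qualifier: note}
        - {name: "5'_PARTIAL", kind: yes_no,  requirement: mandatory, feature: intron, rule: intron_location}
        - {name: "3'_PARTIAL", kind: yes_no,  requirement: mandatory, feature: intron, rule: intron_location}
        - {name: "5'_INTRON",  kind: integer, requirement: mandatory, feature: intron, rule: intron_location}
        - {name: "3'_INTRON",  kind: integer, requirement: mandatory, feature: intron, rule: intron_location}
        - {name: NUMBER,     kind: integer, requirement: mandatory, feature: intron, qualifier: number}
      - *optional_common
      - *universal_tail

  IGS:
    description: any intergenic spacer (e.g. trnH-psbA)
    ena_accession: ""
    synonyms: [trnH, psbA, trnL, trnF, atpB, rbcL, spacer, IGS]
    columns:
      - *universal_head
      - - {name: GENE1,     kind: text,   requirement: mandatory, feature: misc_feature, qualifier: product, rule: igs_product}
        - {name: G1PRESENT, kind: yes_no, requirement: mandatory, feature: gene,         qualifier: note,    rule: gene_presence}
        - {name: GENE2,     kind: text,   requirement: mandatory, feature: misc_feature, qualifier: product, rule: igs_product}
        - {name: G2PRESENT, kind: yes_no, requirement: mandatory, feature: gene,         qualifier: note,    rule: gene_presence}
      - *optional_common
      - *universal_tail

  trnK_matK:
    description: plastid trnK/matK gene region
    ena_accession: ""
    synonyms: [matK, trnK, trnK-UUU]
    columns:
      - *universal_head
      - - {name: "5'_CDS",     kind: yes_no, requirement: mandatory, feature: gene, qualifier: note, rule: cds_location}
        - {name: "3'_CDS",     kind: yes_no, requirement: mandatory, feature: gene, qualifier: note, rule: cds_location}
        - {name: "5'_PARTIAL", kind: yes_no, requirement: mandatory, feature: gene, qualifier: note, rule: cds_location}
        - {name: "3'_PARTIAL", kind: yes_no, requirement: mandatory, feature: gene, qualifier: note, rule: cds_location}
        - {name: INTRON,     kind: yes_no, requirement: mandatory, feature: "intron, tRNA", qualifier: gene, rule: intron_or_trna}
      - *optional_common
      - *universal_tail

  rRNA:
    description: 18S/28S/5.8S nuclear ribosomal rDNA gene
    ena_accession: ""
    synonyms: ["5S", "5.8S", "12S", "16S", "18S", "23S", "25S", "26S", "28S", rRNA, rDNA]
    columns:
      - *universal_head
      - - {name: SEDIMENT, kind: enum, requirement: mandatory, feature: rRNA, qualifier: product, rule: sediment_token,
           permitted: ["5S", "5.8S", "12S", "16S", "18S", "23S", "25S", "26S", "28S"]}
      - *optional_common
      - *universal_tail

  ITS:
    description: nuclear ribosomal internal transcribed spacer
    ena_accession: ""
    synonyms: [ITS, ITS1, ITS2, "5.8S", "18S", "28S"]
    columns:
      - *universal_head
      - - {name: ISOLATION_SOURCE, kind: text,   requirement: conditional, feature: source,   qualifier: isolation_source, rule: env_mandatory}
        - {name: "18S",            kind: yes_no, requirement: mandatory,   feature: rRNA,     qualifier: gene}
        - {name: ITS1,             kind: yes_no, requirement: mandatory,   feature: misc_RNA, qualifier: note}
        - {name: ITS2,             kind: yes_no, requirement: mandatory,   feature: misc_RNA, qualifier: note}
        - {name: "28S",            kind: yes_no, requirement: mandatory,   feature: rRNA,     qualifier: gene}
      - - {name: "5.8S",           kind: yes_no, requirement: optional,    rule: its_58s_inference}
      - *optional_common
      - *universal_tail

  ETS:
    description: nuclear ribosomal external transcribed spacer
    ena_accession: ""
    synonyms: [ETS, "5' ETS", "3' ETS", "18S", "28S"]
    columns:
      - *universal_head
      - - {name: "18S",    kind: yes_no, requirement: conditional, feature: rRNA,     qualifier: gene, rule: "flank_5'"}
        - {name: ETS_TYPE, kind: enum,   requirement: mandatory,   feature: misc_RNA, qualifier: note, rule: ets_type,
            permitted: ["5'", "3'"]}
        - {name: "28S",    kind: yes_no, requirement: conditional, feature: rRNA,     qualifier: gene, rule: "flank_3'"}
      - *optional_common
      - *universal_tail
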