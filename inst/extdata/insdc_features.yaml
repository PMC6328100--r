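# INSDC feature-table vocabulary used for spell-checking feature keys and
# qualifier names during data processing.  This is a curated subset of the
# public INSDC Feature Table Definition (document version 11.3, 2023) that
# covers the feature classes occurring in plant and fungal DNA-barcoding
# flat files; users may extend it by adding keys or qualifiers below.
#
# Matching is case-sensitive: "rRNA" is a valid key, "rrna" is a near-miss.
version: "INSDC Feature Table Definition 11.3 (curated subset)"
features:
  source:
    qualifiers:
      - organism
      - mol_type
      - organelle
      - isolation_source
      - isolate
      - clone
      - specimen_voucher
      - country
      - collection_date
      - lat_lon
      - PCR_primers
      - strain
      - haplotype
      - ecotype
      - environmental_sample
      - tissue_type
      - host
      - note
      - db_xref
  gene:
    qualifiers: [gene, note, locus_tag, standard_name, pseudo, db_xref]
  intron:
    qualifiers: [gene, note, number, standard_name]
  exon:
    qualifiers: [gene, note, number, standard_name]
  tRNA:
    qualifiers: [gene, note, product, anticodon, standard_name]
  rRNA:
    qualifiers: [gene, note, product, standard_name]
  misc_RNA:
    qualifiers: [gene, note, product, standard_name]
  misc_feature:
    qualifiers: [gene, note, product, standard_name]
  CDS:
    qualifiers:
      - gene
      - note
      - product
      - codon_start
      - transl_table
      - translation
      - protein_id
      - standard_name
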