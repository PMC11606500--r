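# Illustrative semi-supervised gating tree.
# Marker sets are conventional examples of the signatures used for T cell
# gating (major lineage, then functional state); they are placeholders meant
# to be replaced by study-specific lists, not a curated reference panel.
name: T_cell
positive:
  - [CD3D, CD3E, CD3G, CD2]
children:
  - name: CD4_T
    positive:
      - [CD4, IL7R, CD40LG]
    negative:
      - [CD8A, CD8B]
    children:
      - name: Treg
        positive:
          - [FOXP3, IL2RA, CTLA4]
      - name: TH1
        positive:
          - [IFNG, TBX21, CXCR3]
  - name: CD8_T
    positive:
      - [CD8A, CD8B, GZMK]
    negative:
      - [CD4, CD40LG]
    children:
      - name: CD8_effector
        positive:
          - [GZMB, PRF1, GNLY, NKG7]
      - name: CD8_memory
        positive:
          - [IL7R, CCR7, SELL]
  - name: cycling
    positive:
      - [MKI67, TOP2A, STMN1]
  - name: immune_checkpoint
    positive:
      - [PDCD1, CTLA4, HAVCR2, TIGIT, LAG3]
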