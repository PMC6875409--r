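cwlVersion: v1.2
class: CommandLineTool
id: trimmer
doc: Trim sequencing reads by quality
baseCommand: [trimtool, run]
inputs:
  - id: reads
    type: File
    doc: Input reads (FASTQ)
    inputBinding:
      prefix: -i
  - id: quality
    type: int?
    default: 20
    inputBinding:
      prefix: -q
  - id: mode
    type:
      type: enum
      symbols: [fast, sensitive]
    inputBinding:
      prefix: -m
  - id: verbose
    type: boolean?
    inputBinding:
      prefix: -v
  - id: out
    type: string
    doc: Output file name
    inputBinding:
      position: 1
outputs: []
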