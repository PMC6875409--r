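<?xml version="1.0" encoding="UTF-8"?>
<template id="hisat_align" title="Align reads with HISAT2" description="Strips the index file extension so the index prefix is accepted.">
<window>
<filedialog id="hisat_index_raw" label="HISAT2 index file" hint="Any .N.ht2 file of the index"/>
<filedialog id="reads" label="Reads (FASTQ)"/>
<action label="Align"/>
<streambox/>
</window>
<execution>
<script id="hisat_index" argv="${hisat_index_raw}"><![CDATA[
function evaluate(arg1)
  if (string.match(arg1, ".%d.ht2$")) then
    return(string.sub(arg1, 0, arg1:find(".%d.ht2$")-1))
  end
  return(arg1)
end
]]></script>
<execute program="hisat2"><param>-x ${hisat_index}</param><param>-U ${reads}</param></execute>
</execution>
</template>
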