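#!/bin/sh
# Fixture install module: echoes its positional arguments back (one line
# per argument) and writes a marker file into the install directory.
INSTALL_DIR="$1"
echo "ARGC:$#"
i=1
for a in "$@"; do
  echo "ARG${i}:${a}"
  i=$((i+1))
done
mkdir -p "$INSTALL_DIR"
echo installed > "$INSTALL_DIR/marker.txt"
exit 0
### TEMPLATE-BEGIN
# <template id="echo_tool" title="Echo a message">
# <window><input id="msg" label="Message" default="hi"/><action label="Run"/><streambox/></window>
# <execution><execute program="echo"><param>${msg}</param></execute></execution>
# </template>
### TEMPLATE-END
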