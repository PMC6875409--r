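#!/bin/sh
# Fixture install module that always fails: nothing must be registered.
echo "refusing to install" >&2
exit 1
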