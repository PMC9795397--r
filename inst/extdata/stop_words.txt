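# English function words removed from short diagnostic text during
# normalization.  One word per line.
a
an
and
as
at
by
for
from
in
is
it
of
on
or
the
to
was
with
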