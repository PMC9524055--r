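a
about
after
all
also
an
and
are
as
at
be
been
but
by
can
could
day
do
for
from
has
have
he
her
his
how
i
if
in
into
is
it
its
just
like
more
my
new
no
not
now
of
on
one
or
our
out
over
rt
she
so
some
than
that
the
their
them
then
there
they
this
to
today
up
us
was
we
were
what
when
which
who
will
with
you
your
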