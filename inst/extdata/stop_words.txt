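# Standard English stop words (snowball-style) plus de-apostrophized
# contraction forms as they appear after punctuation stripping.
# One token per line; lines starting with '#' are comments.
i
me
my
myself
we
our
ours
ourselves
you
your
yours
yourself
yourselves
he
him
his
himself
she
her
hers
herself
it
its
itself
they
them
their
theirs
themselves
what
which
who
whom
this
that
these
those
am
is
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
would
should
could
ought
a
an
the
and
but
if
or
because
as
until
while
of
at
by
for
with
about
into
through
during
to
from
up
down
in
out
on
off
again
further
then
once
here
there
when
where
why
how
all
any
both
each
few
more
most
other
some
such
nor
only
own
same
so
than
too
very
s
t
can
will
just
now
between
against
before
after
above
below
not
no
im
youre
theyre
ive
youve
weve
theyve
youd
theyd
youll
theyll
isnt
arent
wasnt
werent
hasnt
havent
hadnt
doesnt
dont
didnt
wont
wouldnt
shant
shouldnt
cant
cannot
couldnt
mustnt
lets
thats
whos
whats
heres
theres
wheres
hows
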