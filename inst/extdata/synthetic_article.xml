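<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic JATS example article (constructed for format tests; not a real publication) -->
<article article-type="research-article">
  <front>
    <journal-meta>
      <journal-title>Journal of Synthetic Examples</journal-title>
    </journal-meta>
    <article-meta>
      <article-id pub-id-type="pmc">SYNTH0001</article-id>
      <article-title>A synthetic study of text reuse detection</article-title>
      <contrib-group>
        <contrib contrib-type="author">
          <name><surname>Smith</surname><given-names>John A.</given-names></name>
        </contrib>
        <contrib contrib-type="author">
          <name><surname>Garc&#237;a</surname><given-names>Mar&#237;a</given-names></name>
        </contrib>
      </contrib-group>
      <pub-date><year>2008</year></pub-date>
      <abstract>
        <p>We describe a synthetic abstract used to exercise the article parser.
        It contains plain sentences and no markup beyond paragraphs.</p>
      </abstract>
    </article-meta>
  </front>
  <body>
    <sec>
      <title>Background</title>
      <p>The first background paragraph describes prior work on duplicate detection.</p>
      <p>The second background paragraph motivates full text comparison.</p>
    </sec>
    <sec>
      <title>Materials and Methods</title>
      <p>Texts were tokenized and compared with a weighted overlap score.</p>
      <p>A similarity ratio threshold of 0.5 was applied to all pairs.</p>
    </sec>
    <sec>
      <title>Results and Discussion</title>
      <p>Planted duplicates were recovered at the expected rates.</p>
    </sec>
  </body>
</article>
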