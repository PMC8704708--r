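-- Portable DDL for the eight-table relational layout of the unified food
-- composition database. The reference store in this package is a directory
-- of CSV files with these columns; the DDL documents the same schema for
-- loading into any SQL engine.

CREATE TABLE sources (
  source_id       VARCHAR(16) PRIMARY KEY,
  name            TEXT NOT NULL,
  country_or_org  TEXT,
  version_date    TEXT,
  notes           TEXT
);

CREATE TABLE components (
  tagname         VARCHAR(32) PRIMARY KEY,  -- INFOODS-style token
  display_name    TEXT NOT NULL,
  standard_unit   VARCHAR(8) NOT NULL,      -- g | mg | ug | kcal | kJ
  component_class VARCHAR(16) NOT NULL,
  tagname_origin  VARCHAR(24) NOT NULL      -- infoods_standard | compiler_assigned
);

CREATE TABLE foods (
  foodex2        CHAR(5) NOT NULL,          -- FoodEx2 classification code
  basis          VARCHAR(10) NOT NULL,      -- per_100g | per_100mL
  name           TEXT,
  food_group     TEXT,
  cooking_method TEXT,
  edible_portion DOUBLE PRECISION,
  n_records      INTEGER,
  n_source_dbs   INTEGER,
  matched        BOOLEAN,                   -- unified across >= 2 sources
  PRIMARY KEY (foodex2, basis)
);

-- One row per contributing source value. Unified statistics (n, mean,
-- median, sd, chosen) are carried on each contributor row; rows with NULL
-- source_id are provenance-free values (reinstated logical zeros,
-- recalculated energy).
CREATE TABLE component_values (
  foodex2          CHAR(5) NOT NULL,
  basis            VARCHAR(10) NOT NULL,
  tagname          VARCHAR(32) NOT NULL REFERENCES components,
  source_id        VARCHAR(16) REFERENCES sources,
  original_food_id TEXT,                    -- verbatim source identifier
  raw_value        DOUBLE PRECISION,        -- in raw_unit, pre-conversion
  raw_unit         VARCHAR(8),
  value_std        DOUBLE PRECISION,        -- standard unit, in the pool
  contributor_outlier_flag BOOLEAN,
  n_sources        INTEGER NOT NULL,
  mean             DOUBLE PRECISION,
  median           DOUBLE PRECISION,
  sd               DOUBLE PRECISION,
  chosen           DOUBLE PRECISION,        -- rounded median
  logical_zero     BOOLEAN,
  review_flag      BOOLEAN,
  FOREIGN KEY (foodex2, basis) REFERENCES foods
);

CREATE TABLE yield_factors (
  food_group     TEXT NOT NULL,             -- or 'ANY'
  cooking_method TEXT NOT NULL,
  yf             DOUBLE PRECISION NOT NULL CHECK (yf > 0)
);

CREATE TABLE retention_factors (
  component      TEXT NOT NULL,             -- tagname or component class
  level          VARCHAR(8) NOT NULL,       -- 'tagname' | 'class'
  food_group     TEXT NOT NULL,             -- or 'ANY'
  cooking_method TEXT NOT NULL,
  rf             DOUBLE PRECISION NOT NULL CHECK (rf >= 0 AND rf <= 2)
);

CREATE TABLE recipes (
  recipe_id      VARCHAR(16) PRIMARY KEY,
  name           TEXT,
  cooking_method TEXT NOT NULL,
  yf_override    DOUBLE PRECISION
);

CREATE TABLE recipe_ingredients (
  recipe_id      VARCHAR(16) NOT NULL REFERENCES recipes,
  foodex2        CHAR(5) NOT NULL,
  raw_weight     DOUBLE PRECISION NOT NULL CHECK (raw_weight > 0),
  edible_portion DOUBLE PRECISION
);
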